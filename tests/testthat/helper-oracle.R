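# Independent brute-force oracle for the adjacency-adjusted sum score, written
# before and kept independent of compute_olvfss(). Plain per-position loops:
# suppression first, then greedy left-to-right pairing of surviving minimals
# (a pair of adjacent minimals counts -0.5, a leftover single counts -0.5,
# which reproduces -0.5 * ceiling(k/2) on a run of length k).
oracle_olvfss <- function(s) {
  stopifnot(length(s) == 15)
  s <- unname(s)
  suppressed <- rep(FALSE, 15)
  for (i in 1:15) {
    if (s[i] == -0.5) {
      left_severe <- i > 1 && s[i - 1] <= -1
      right_severe <- i < 15 && s[i + 1] <= -1
      if (left_severe || right_severe) suppressed[i] <- TRUE
    }
  }
  total <- 0
  for (i in 1:15) if (s[i] != -0.5) total <- total + s[i]
  i <- 1
  while (i <= 15) {
    if (s[i] == -0.5 && !suppressed[i]) {
      if (i < 15 && s[i + 1] == -0.5 && !suppressed[i + 1]) {
        total <- total - 0.5   # pair consumed together
        i <- i + 2
      } else {
        total <- total - 0.5
        i <- i + 1
      }
    } else {
      i <- i + 1
    }
  }
  total
}

# random valid spine as a named score vector
random_spine <- function(max_deformities = 6) {
  k <- sample(0:max_deformities, 1)
  if (k == 0) return(numeric(0))
  pos <- sample(vertebral_levels(), k)
  stats::setNames(sample(c(-0.5, -1, -1.5, -2, -2.5, -3), k, replace = TRUE), pos)
}
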