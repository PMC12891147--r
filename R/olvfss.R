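# OLVF sum score over T3-L5 with the adjacency adjustment rules:
#   suppression: a minimal-grade (-0.5) vertebra adjacent to a vertebra scored
#     <= -1.0 contributes nothing (the severe neighbour carries the burden);
#   run merging: a maximal run of k >= 2 surviving adjacent minimal vertebrae
#     contributes -0.5 * ceiling(k/2) instead of -0.5 * k (two adjacent
#     minimals count -0.5, three count -1.0).
# Suppression is applied before run merging.

.allowed_scores <- c(0, -0.5, -1, -1.5, -2, -2.5, -3)

#' Construct a validated spine assessment
#'
#' A spine assessment is a full-length named numeric vector of per-vertebra eSQ
#' scores over the 15 levels T3-L5. Input may name any subset of levels; absent
#' levels score 0. Levels outside T3-L5 (e.g. T1, T2) are rejected rather than
#' silently dropped.
#'
#' @param scores named numeric vector; names are level labels, values eSQ
#'   scores in \{0, -0.5, -1, -1.5, -2, -2.5, -3\}. An empty vector is a spine
#'   with no deformity.
#' @return Named numeric vector of length 15 in anatomical order.
#' @examples
#' spine_assessment(c(T12 = -0.5, L1 = -2))
#' @export
spine_assessment <- function(scores = numeric(0)) {
  lv <- vertebral_levels()
  full <- stats::setNames(numeric(15), lv)
  if (length(scores)) {
    if (is.null(names(scores)) || any(!nzchar(names(scores)))) {
      stop("scores must be named by vertebral level", call. = FALSE)
    }
    idx <- level_index(names(scores))
    if (anyDuplicated(idx)) {
      stop("duplicate vertebral levels in assessment", call. = FALSE)
    }
    if (!all(scores %in% .allowed_scores)) {
      stop("scores must be in {0, -0.5, -1, -1.5, -2, -2.5, -3}", call. = FALSE)
    }
    full[idx] <- as.numeric(scores)
  }
  full
}

# internal: coerce vector/matrix input to a validated n x 15 score matrix
.score_matrix <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) != 15L) stop("score matrix must have 15 columns (T3-L5)", call. = FALSE)
    if (!all(x %in% .allowed_scores)) {
      stop("scores must be in {0, -0.5, -1, -1.5, -2, -2.5, -3}", call. = FALSE)
    }
    x
  } else {
    matrix(spine_assessment(x), nrow = 1)
  }
}

#' OLVF sum score (OLVFss) over T3-L5
#'
#' Sums per-vertebra eSQ scores over T3-L5 after two adjacency adjustments,
#' applied in this order: first every minimal-grade (-0.5) vertebra adjacent to
#' a vertebra scored at or below -1.0 is suppressed (contributes 0); then each
#' maximal run of k >= 2 surviving adjacent minimal vertebrae contributes
#' -0.5 * ceiling(k/2) in place of -0.5 * k. All non-minimal scores contribute
#' their face value. The result lies in \[-45, 0\] in steps of 0.5; a more
#' negative score means a heavier deformity burden.
#'
#' @param scores a named per-level score vector as accepted by
#'   [spine_assessment()], or a numeric matrix with one spine per row and 15
#'   columns in anatomical order (T3...L5) for vectorised scoring.
#' @return Numeric vector of sum scores (length 1 for vector input, one per
#'   row for matrix input).
#' @examples
#' compute_olvfss(c(T12 = -0.5, L1 = -2))      # suppression: -2.0, not -2.5
#' compute_olvfss(c(T5 = -0.5, T6 = -0.5))     # two adjacent minimals: -0.5
#' compute_olvfss(c(T5 = -0.5, T6 = -0.5, T7 = -0.5))  # three: -1.0
#' @export
compute_olvfss <- function(scores) {
  m <- .score_matrix(scores)
  n <- nrow(m)
  minimal <- m == -0.5
  severe <- m <= -1
  pad <- matrix(FALSE, n, 1)
  next_severe <- cbind(severe[, -1, drop = FALSE], pad)
  prev_severe <- cbind(pad, severe[, -15, drop = FALSE])
  severe_neigh <- next_severe | prev_severe
  surviving <- minimal & !severe_neigh
  # run lengths of surviving minimals, all rows at once: flatten row-wise with a
  # FALSE separator column so runs cannot straddle rows
  flat <- as.vector(t(cbind(surviving, pad)))
  r <- rle(flat)
  k <- r$lengths[r$values]
  run_contrib <- -0.5 * ceiling(k / 2)
  # row of each run, from the flattened index of the run start
  start <- (cumsum(r$lengths) - r$lengths + 1L)[r$values]
  row_of <- (start - 1L) %/% 16L + 1L
  base <- rowSums(m * !minimal)
  runs <- numeric(n)
  if (length(run_contrib)) {
    agg <- vapply(split(run_contrib, row_of), sum, numeric(1))
    runs[as.integer(names(agg))] <- agg
  }
  unname(base + runs)
}

#' Most severe single OLVF score
#'
#' The minimum raw per-vertebra score of an assessment (before any adjacency
#' adjustment), 0 when no deformity is present. Severity thresholds such as
#' "most severe OLVF score being -3.0" (a collapsed vertebra, >= 2/3 height
#' loss) describe individual deformities and therefore use raw scores.
#'
#' @inheritParams compute_olvfss
#' @return Numeric vector of minimum scores.
#' @examples
#' most_severe_olvf(c(T7 = -3, L3 = -1))
#' @export
most_severe_olvf <- function(scores) {
  m <- .score_matrix(scores)
  unname(do.call(pmin, as.data.frame(m)))
}

#' Number of deformed vertebrae in an assessment
#'
#' @inheritParams compute_olvfss
#' @return Integer count of vertebrae with a nonzero score.
#' @export
n_olvf <- function(scores) {
  m <- .score_matrix(scores)
  unname(as.integer(rowSums(m != 0)))
}
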