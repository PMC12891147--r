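test_that("height loss is interpolated from the nearest normal neighbours", {
  spine <- data.frame(level = c("T11", "L1", "L2"),
                      anterior_mm = c(30, 20, 30),
                      middle_mm = c(28, 28, 28),
                      posterior_mm = c(29, 29, 29))
  expect_equal(estimate_height_loss(spine, "L1", c("T11", "L2")), 1 / 3,
               tolerance = 1e-12)

  # equidistant references one level away: expected height is their midpoint
  spine2 <- data.frame(level = c("T9", "T10", "T11"),
                       anterior_mm = c(28, 10, 32),
                       middle_mm = c(25, 25, 25),
                       posterior_mm = c(26, 26, 26))
  expect_equal(estimate_height_loss(spine2, "T10", c("T9", "T11")), 1 - 10 / 30)

  # no deformity: measured equals expected at every position
  spine3 <- spine2; spine3$anterior_mm <- c(28, 30, 32)
  expect_equal(estimate_height_loss(spine3, "T10", c("T9", "T11")), 0)
})

test_that("one-sided references carry the nearest normal height", {
  spine <- data.frame(level = c("L3", "L4", "L5"),
                      anterior_mm = c(30, 31, 20),
                      middle_mm = c(30, 31, 31),
                      posterior_mm = c(30, 31, 31))
  # L5 has references above only: expected anterior carried from L4 (31)
  expect_equal(estimate_height_loss(spine, "L5", c("L3", "L4")), 1 - 20 / 31)
})

test_that("height-loss estimation validates its inputs", {
  spine <- data.frame(level = c("T9", "T10"), anterior_mm = c(28, 20),
                      middle_mm = c(28, 20), posterior_mm = c(28, 20))
  expect_error(estimate_height_loss(spine, "T11", "T9"), "absent")
  expect_error(estimate_height_loss(spine, "T10", character(0)), "reference")
  expect_error(estimate_height_loss(spine, "T10", "T10"), "reference")
  spine$anterior_mm[1] <- -1
  expect_error(estimate_height_loss(spine, "T10", "T9"), "positive")
})

test_that("height loss is scale invariant", {
  set.seed(42)
  for (rep in 1:20) {
    lv <- sort(sample(15, 6))
    spine <- data.frame(level = vertebral_levels()[lv],
                        anterior_mm = runif(6, 15, 35),
                        middle_mm = runif(6, 15, 35),
                        posterior_mm = runif(6, 15, 35))
    normal <- spine$level[c(1, 3, 6)]
    target <- spine$level[4]
    l1 <- estimate_height_loss(spine, target, normal)
    spine2 <- spine
    spine2[2:4] <- spine2[2:4] * 3.7
    expect_equal(estimate_height_loss(spine2, target, normal), l1,
                 tolerance = 1e-12)
  }
})

test_that("grades map height loss, reader flags and scores as specified", {
  g <- assign_esq_grade(c(0.22, 0.10, 0.70, 0.30, 0),
                        fracture_like = c(TRUE, FALSE, TRUE, TRUE, TRUE),
                        non_fracture_cause = c(FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(g$grade, c("mild", "none", "collapsed", "none", "none"))
  expect_equal(g$score, c(-1, 0, -3, 0, 0))

  # sub-20% loss needs the fracture-like judgement; >= 20% is graded regardless
  expect_equal(assign_esq_grade(0.15, fracture_like = TRUE)$grade, "minimal")
  expect_equal(assign_esq_grade(0.15, fracture_like = FALSE)$grade, "none")
  expect_equal(assign_esq_grade(0.25, fracture_like = FALSE)$grade, "moderate")

  expect_error(assign_esq_grade(1.2), "\\[0, 1\\]")
  expect_error(assign_esq_grade(-0.1), "\\[0, 1\\]")
})

test_that("band boundaries are closed on the left, with exact thirds", {
  edges <- c(0.20, 0.25, 1 / 3, 0.40, 2 / 3)
  expected <- c("mild", "moderate", "moderately_severe", "severe", "collapsed")
  got <- assign_esq_grade(edges, fracture_like = FALSE)
  expect_equal(got$grade, expected)
  # just below each edge falls in the previous band
  below <- assign_esq_grade(edges - 1e-9, fracture_like = TRUE)
  expect_equal(below$grade,
               c("minimal", "mild", "moderate", "moderately_severe", "severe"))
})

test_that("grading is monotone in height loss and lands in the score set", {
  loss <- seq(0, 1, by = 0.005)
  sc <- assign_esq_grade(loss, fracture_like = TRUE)$score
  expect_true(all(diff(sc) <= 0))
  expect_true(all(sc %in% c(0, -0.5, -1, -1.5, -2, -2.5, -3)))
  # grade<->score bijection on outputs
  tab <- esq_grade_table()
  g <- assign_esq_grade(loss, fracture_like = TRUE)
  expect_equal(g$score, tab$score[match(g$grade, tab$grade)])
})
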