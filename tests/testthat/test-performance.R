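make_subjects <- function(n_fx, n_ctrl, fx_pos, ctrl_pos, horizon = 5) {
  # minimal scored cohort: positivity carried by olvfss (-2 positive at <= -1.5)
  data.frame(
    subject_id = sprintf("S%04d", seq_len(n_fx + n_ctrl)),
    sex = "female", age_years = 75,
    fn_tscore = -1, ls_tscore = -1,
    olvfss = c(rep(-2, fx_pos), rep(0, n_fx - fx_pos),
               rep(-2, ctrl_pos), rep(0, n_ctrl - ctrl_pos)),
    most_severe_olvf = 0, n_olvf = 0,
    hip_fx = rep(c(TRUE, FALSE), c(n_fx, n_ctrl)),
    fx_time_years = c(rep(2, n_fx), rep(NA_real_, n_ctrl)),
    death_time_years = NA_real_, followup_years = horizon,
    stringsAsFactors = FALSE
  )
}
olvfss_metric <- metric_definition("OLVFss -1.5", "olvfss", -1.5)

test_that("analysis set applies the listwise death rule", {
  s <- data.frame(hip_fx = c(FALSE, TRUE, FALSE, TRUE),
                  fx_time_years = c(NA, 2, NA, 6),
                  death_time_years = c(2, 3, NA, NA),
                  followup_years = 5)
  a <- analysis_set(s, 5)
  # death at year 2 without fracture: excluded; fracture-then-death: kept
  expect_equal(nrow(a), 3)
  expect_equal(a$fx_event, c(TRUE, FALSE, FALSE))  # year-6 fracture beyond horizon
  # at a 1.5-year horizon the year-2 death survived to the horizon: all kept
  expect_equal(nrow(analysis_set(s, 1.5)), 4)
  expect_equal(sum(analysis_set(s, 1.5)$fx_event), 0)
  expect_error(analysis_set(s, -1), "positive")
  bad <- data.frame(hip_fx = TRUE, fx_time_years = 3, death_time_years = 2,
                    followup_years = 5)
  expect_error(analysis_set(bad, 5), "postdate")
})

test_that("ppv and sensitivity reproduce the defining mini-examples", {
  # 10 positives of whom 2 fracture -> PPV 20%
  s <- make_subjects(n_fx = 2, n_ctrl = 98, fx_pos = 2, ctrl_pos = 8)
  r <- evaluate_metric(s, olvfss_metric, 5)
  expect_equal(r$n_positive, 10)
  expect_equal(r$ppv, 20)
  # 10 fracture cases of whom 7 positive -> sensitivity 70%
  s2 <- make_subjects(n_fx = 10, n_ctrl = 90, fx_pos = 7, ctrl_pos = 13)
  r2 <- evaluate_metric(s2, olvfss_metric, 5)
  expect_equal(r2$n_fx, 10)
  expect_equal(r2$sensitivity, 70)
  # counts conserve: positives and fracture cases partition over TP
  expect_equal(r2$n_true_positive + (r2$n_fx - r2$n_true_positive), r2$n_fx)
  expect_equal(r2$n_analysis, 100)
})

test_that("undefined denominators give NA, not zero", {
  s <- make_subjects(n_fx = 2, n_ctrl = 98, fx_pos = 0, ctrl_pos = 0)
  r <- evaluate_metric(s, olvfss_metric, 5)
  expect_true(is.na(r$ppv))
  expect_equal(r$sensitivity, 0)
  s2 <- make_subjects(n_fx = 0, n_ctrl = 50, fx_pos = 0, ctrl_pos = 5)
  r2 <- evaluate_metric(s2, olvfss_metric, 5)
  expect_true(is.na(r2$sensitivity))
  expect_equal(r2$ppv, 0)
})

test_that("unevaluable subjects drop from numerator and denominator", {
  s <- make_subjects(n_fx = 4, n_ctrl = 96, fx_pos = 2, ctrl_pos = 10)
  s$ls_tscore <- -4; s$ls_tscore[1] <- NA  # one Fx case unmeasured
  m <- metric_definition("spine T -3.7", "ls_tscore", -3.7)
  r <- evaluate_metric(s, m, 5)
  expect_equal(r$n_analysis, 99)
  expect_equal(r$n_fx, 3)
  expect_equal(r$sensitivity, 100)
})

test_that("risk ratio is identically ppv / incidence", {
  set.seed(31)
  for (i in 1:20) {
    n_fx <- sample(2:10, 1); n_ctrl <- sample(50:200, 1)
    s <- make_subjects(n_fx, n_ctrl, fx_pos = sample(n_fx, 1),
                       ctrl_pos = sample(n_ctrl %/% 2, 1))
    r <- evaluate_metric(s, olvfss_metric, 5)
    expect_equal(r$risk_ratio, r$ppv / r$incidence, tolerance = 1e-12)
  }
})

test_that("events accumulate with the horizon", {
  s <- make_subjects(n_fx = 10, n_ctrl = 90, fx_pos = 5, ctrl_pos = 10)
  s$fx_time_years[1:10] <- c(rep(1, 3), rep(4, 7))
  r3 <- evaluate_metric(s, olvfss_metric, 3)
  r5 <- evaluate_metric(s, olvfss_metric, 5)
  expect_lte(r3$n_fx, r5$n_fx)
  expect_equal(r3$n_fx, 3)
  expect_equal(r5$n_fx, 10)
  expect_equal(hip_fx_incidence(s, 5), 10)
})

test_that("degenerate cutpoints behave as limits", {
  s <- make_subjects(n_fx = 5, n_ctrl = 95, fx_pos = 3, ctrl_pos = 10)
  never <- metric_definition("never", "olvfss", -Inf)
  r <- evaluate_metric(s, never, 5)
  expect_equal(r$sensitivity, 0)
  expect_true(is.na(r$ppv))
  always <- metric_definition("always", "olvfss", Inf)
  ra <- evaluate_metric(s, always, 5)
  expect_equal(ra$ppv, ra$incidence)
  expect_equal(ra$risk_ratio, 1)
})

test_that("performance tables have one ordered row per metric x horizon", {
  s <- make_subjects(n_fx = 5, n_ctrl = 95, fx_pos = 3, ctrl_pos = 10)
  s$most_severe_olvf <- ifelse(s$olvfss < 0, -2, 0)
  tab <- performance_table(s, builtin_metrics("female"), c(5, 3))
  expect_equal(nrow(tab), 12)
  expect_equal(tab$horizon_years, rep(c(3, 5), 6))
  expect_equal(tab$metric_name[1:2], rep("neck T -2.7", 2))
  expect_equal(nrow(performance_table(s, list(), c(3, 5))), 0)
})
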