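# Sex-specific baseline positivity metrics: DXA T-score cutpoints calibrated
# for older Chinese community subjects, plus OLVF-derived score thresholds.
# T-scores are inputs (computed elsewhere against local reference curves);
# this module only applies cutpoints.

.metric_quantities <- c("fn_tscore", "ls_tscore", "olvfss", "most_severe_olvf")

#' Define a baseline positivity metric
#'
#' @param name short label used in reports.
#' @param quantity one of `"fn_tscore"`, `"ls_tscore"` (DXA T-scores at the
#'   femoral neck / lumbar spine L1-L4), `"olvfss"`, or `"most_severe_olvf"`.
#' @param cutpoint numeric threshold.
#' @param comparison `"at_or_below"` (positive when quantity <= cutpoint) or
#'   `"exactly"` (positive when quantity == cutpoint; used for the score floor
#'   -3.0, where it coincides with at-or-below).
#' @return An object of class `olvf_metric`.
#' @examples
#' metric_definition("neck T -2.7", "fn_tscore", -2.7)
#' @export
metric_definition <- function(name, quantity, cutpoint,
                              comparison = c("at_or_below", "exactly")) {
  comparison <- match.arg(comparison)
  quantity <- match.arg(quantity, .metric_quantities)
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(cutpoint), length(cutpoint) == 1L, is.finite(cutpoint) ||
              is.infinite(cutpoint))
  structure(list(name = name, quantity = quantity, cutpoint = cutpoint,
                 comparison = comparison),
            class = "olvf_metric")
}

#' @export
print.olvf_metric <- function(x, ...) {
  op <- if (x$comparison == "exactly") "==" else "<="
  cat(sprintf("<olvf_metric> %s: %s %s %g\n", x$name, x$quantity, op, x$cutpoint))
  invisible(x)
}

#' Built-in baseline metrics by sex
#'
#' The sex-specific metric sets evaluated against five-year hip-fracture
#' follow-up. Women: femoral-neck T-score <= -2.7 (osteoporosis cutpoint for
#' Chinese women; the reference metric), lumbar-spine T-score <= -3.7 and
#' <= -2.5, OLVFss <= -1.5, most severe OLVF score exactly -3.0 (collapsed) and
#' <= -2.5. Men: femoral-neck T-score <= -2.1 (osteofrailia cutpoint for
#' Chinese men), lumbar-spine T-score <= -2.5, OLVFss <= -2.0 / -2.5 / -3.0,
#' and most severe OLVF score <= -2.0, <= -2.5, exactly -3.0.
#'
#' @param sex `"female"` or `"male"`.
#' @return List of [metric_definition()] objects.
#' @examples
#' names(builtin_metrics("female"))
#' @export
builtin_metrics <- function(sex = c("female", "male")) {
  sex <- match.arg(sex)
  defs <- if (sex == "female") {
    list(
      metric_definition("neck T -2.7",    "fn_tscore",        -2.7),
      metric_definition("spine T -3.7",   "ls_tscore",        -3.7),
      metric_definition("spine T -2.5",   "ls_tscore",        -2.5),
      metric_definition("OLVFss -1.5",    "olvfss",           -1.5),
      metric_definition("OLVF hi-3",      "most_severe_olvf", -3, "exactly"),
      metric_definition("OLVF hi-2.5",    "most_severe_olvf", -2.5)
    )
  } else {
    list(
      metric_definition("neck T -2.1",    "fn_tscore",        -2.1),
      metric_definition("spine T -2.5",   "ls_tscore",        -2.5),
      metric_definition("OLVFss -2",      "olvfss",           -2),
      metric_definition("OLVFss -2.5",    "olvfss",           -2.5),
      metric_definition("OLVFss -3",      "olvfss",           -3),
      metric_definition("OLVF hi-2.0",    "most_severe_olvf", -2),
      metric_definition("OLVF hi-2.5",    "most_severe_olvf", -2.5),
      metric_definition("OLVF hi-3",      "most_severe_olvf", -3, "exactly")
    )
  }
  stats::setNames(defs, vapply(defs, `[[`, character(1), "name"))
}

#' Classify subjects against a metric
#'
#' Applies a metric's cutpoint to the relevant quantity of each subject.
#' A missing quantity (e.g. an unmeasured lumbar-spine T-score) yields
#' `"unevaluable"`, not an error; unevaluable subjects are excluded metric-wise
#' from performance denominators downstream.
#'
#' @param subjects data.frame of (scored) subject records carrying the metric's
#'   quantity column.
#' @param metric an [metric_definition()] object.
#' @return Factor with levels `positive`, `negative`, `unevaluable`.
#' @examples
#' s <- data.frame(fn_tscore = c(-2.7, -2.0, NA))
#' classify(s, metric_definition("neck T -2.7", "fn_tscore", -2.7))
#' @export
classify <- function(subjects, metric) {
  stopifnot(inherits(metric, "olvf_metric"))
  if (!metric$quantity %in% names(subjects)) {
    stop("subjects lack column '", metric$quantity,
         "'; score the cohort first (see score_subjects())", call. = FALSE)
  }
  q <- subjects[[metric$quantity]]
  pos <- if (metric$comparison == "exactly") q == metric$cutpoint else q <= metric$cutpoint
  out <- ifelse(is.na(q), "unevaluable", ifelse(pos, "positive", "negative"))
  factor(out, levels = c("positive", "negative", "unevaluable"))
}
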