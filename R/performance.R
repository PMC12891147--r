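# Crude screening operating characteristics over prospective follow-up.
# The analysis set replicates the cohort's listwise death rule: a subject who
# died before the horizon without a prior hip fracture is excluded; a subject
# who fractured and later died stays in with the event. No person-time
# denominators, matching crude percentage reporting.

#' Build the analysis set for a follow-up horizon
#'
#' Keeps every subject who either sustained a hip fracture at or before the
#' horizon, or survived (was not known dead) to the horizon; drops subjects who
#' died before the horizon without a prior hip fracture.
#'
#' @param subjects data.frame of subject records with logical `hip_fx` and
#'   numeric `fx_time_years`, `death_time_years` (NA when absent).
#' @param horizon_years positive follow-up horizon in years.
#' @return The subset data.frame, with a logical column `fx_event` marking a
#'   hip fracture within the horizon.
#' @examples
#' s <- data.frame(hip_fx = c(FALSE, TRUE, FALSE),
#'                 fx_time_years = c(NA, 2, NA),
#'                 death_time_years = c(2, 3, NA))
#' nrow(analysis_set(s, 5))  # the year-2 death without fracture is excluded
#' @export
analysis_set <- function(subjects, horizon_years) {
  if (!is.numeric(horizon_years) || length(horizon_years) != 1L ||
      is.na(horizon_years) || horizon_years <= 0) {
    stop("horizon_years must be a single positive number", call. = FALSE)
  }
  need <- c("hip_fx", "fx_time_years", "death_time_years")
  if (!all(need %in% names(subjects))) {
    stop("subjects must carry columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  fx_time <- subjects$fx_time_years
  if (any(subjects$hip_fx & is.na(fx_time))) {
    stop("hip_fx = TRUE requires fx_time_years", call. = FALSE)
  }
  bad <- subjects$hip_fx & !is.na(subjects$death_time_years) &
    subjects$death_time_years < fx_time
  if (any(bad, na.rm = TRUE)) {
    stop("death_time_years precedes fx_time_years for ", sum(bad),
         " subject(s); a fracture cannot postdate death", call. = FALSE)
  }
  event <- subjects$hip_fx & fx_time <= horizon_years
  event[is.na(event)] <- FALSE
  survived <- is.na(subjects$death_time_years) |
    subjects$death_time_years >= horizon_years
  keep <- event | survived
  out <- subjects[keep, , drop = FALSE]
  out$fx_event <- event[keep]
  out
}

#' Crude hip-fracture incidence over a horizon
#'
#' @inheritParams analysis_set
#' @return Percentage: 100 x (fracture events within horizon) / (analysis-set
#'   size).
#' @examples
#' \dontrun{hip_fx_incidence(cohort$subjects, 5)}
#' @export
hip_fx_incidence <- function(subjects, horizon_years) {
  a <- analysis_set(subjects, horizon_years)
  if (nrow(a) == 0L) stop("empty analysis set", call. = FALSE)
  100 * sum(a$fx_event) / nrow(a)
}

#' Evaluate one metric's screening performance
#'
#' Over the horizon's analysis set, restricted to subjects evaluable for the
#' metric, counts baseline positives, hip-fracture events, and their overlap,
#' and derives:
#' * positive predictive value `ppv` = 100 x true positives / positives
#'   (percentage of baseline-positive subjects who fracture; NA when there are
#'   no positives);
#' * detection sensitivity = 100 x true positives / fracture cases (percentage
#'   of fracture cases that were baseline-positive; NA when no cases);
#' * crude incidence = 100 x fracture cases / analysis-set size;
#' * risk ratio = ppv / incidence (fracture risk among positives relative to
#'   the whole analysis population).
#'
#' @inheritParams analysis_set
#' @param metric a [metric_definition()].
#' @return One-row data.frame (class `olvf_performance`) with columns
#'   `metric_name`, `horizon_years`, `n_analysis`, `n_positive`, `n_fx`,
#'   `n_true_positive`, `ppv`, `sensitivity`, `incidence`, `risk_ratio`.
#' @export
evaluate_metric <- function(subjects, metric, horizon_years) {
  stopifnot(inherits(metric, "olvf_metric"))
  a <- analysis_set(subjects, horizon_years)
  status <- classify(a, metric)
  a <- a[status != "unevaluable", , drop = FALSE]
  status <- status[status != "unevaluable"]
  n <- nrow(a)
  if (n == 0L) stop("no evaluable subjects for metric '", metric$name, "'",
                    call. = FALSE)
  n_pos <- sum(status == "positive")
  n_fx <- sum(a$fx_event)
  n_tp <- sum(status == "positive" & a$fx_event)
  ppv <- if (n_pos > 0) 100 * n_tp / n_pos else NA_real_
  sens <- if (n_fx > 0) 100 * n_tp / n_fx else NA_real_
  inc <- 100 * n_fx / n
  out <- data.frame(metric_name = metric$name, horizon_years = horizon_years,
                    n_analysis = n, n_positive = n_pos, n_fx = n_fx,
                    n_true_positive = n_tp, ppv = ppv, sensitivity = sens,
                    incidence = inc, risk_ratio = ppv / inc,
                    stringsAsFactors = FALSE)
  class(out) <- c("olvf_performance", class(out))
  out
}

#' Performance table over metrics and horizons
#'
#' @inheritParams analysis_set
#' @param metrics list of [metric_definition()] objects.
#' @param horizons numeric vector of follow-up horizons in years.
#' @return Data.frame with one row per metric x horizon, ordered by metric list
#'   position then ascending horizon.
#' @export
performance_table <- function(subjects, metrics, horizons) {
  horizons <- sort(horizons)
  rows <- list()
  for (m in metrics) {
    for (h in horizons) {
      rows[[length(rows) + 1L]] <- evaluate_metric(subjects, m, h)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(metric_name = character(0), horizon_years = numeric(0),
                      n_analysis = integer(0), n_positive = integer(0),
                      n_fx = integer(0), n_true_positive = integer(0),
                      ppv = numeric(0), sensitivity = numeric(0),
                      incidence = numeric(0), risk_ratio = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
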