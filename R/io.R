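# CSV exchange formats (UTF-8, header row, "." decimal separator):
#   subjects.csv  subject_id, sex, age_years, fn_tscore, ls_tscore, hip_fx,
#                 fx_time_years, death_time_years, followup_years
#                 (blank T-score = missing, excluded metric-wise)
#   vertebrae.csv subject_id, level, then EITHER score, OR height_loss, OR the
#                 three heights anterior_mm/middle_mm/posterior_mm, plus
#                 optional fracture_like, non_fracture_cause reader flags.
# Sexes are never pooled: every computation downstream is sex-stratified.

#' Read a cohort from subjects and vertebrae CSV files
#'
#' Joins vertebra rows to subjects by `subject_id` and converts them to
#' per-subject spine assessments. Vertebra rows may carry an eSQ `score`
#' directly, a fractional `height_loss` (graded via [assign_esq_grade()] with
#' the reader flags), or the three measured heights (losses estimated via
#' [estimate_height_loss()] against the subject's unflagged vertebrae, then
#' graded). Supplying both heights and `height_loss` is an error. Subjects with
#' no vertebra rows get an empty spine (OLVFss 0). Malformed rows are reported
#' with their line numbers.
#'
#' @param subjects_path path to subjects.csv.
#' @param vertebrae_path path to vertebrae.csv, or `NULL` for a cohort with no
#'   deformity data.
#' @return A list of class `olvf_cohort` with `subjects` and `vertebrae`
#'   (normalised to `subject_id`, `level`, `score`).
#' @export
read_cohort <- function(subjects_path, vertebrae_path = NULL) {
  subjects <- utils::read.csv(subjects_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "sex", "age_years", "fn_tscore", "ls_tscore",
            "hip_fx", "fx_time_years", "death_time_years", "followup_years")
  miss <- setdiff(need, names(subjects))
  if (length(miss)) {
    stop("subjects file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(subjects$sex %in% c("female", "male"))) {
    stop("sex must be 'female' or 'male'", call. = FALSE)
  }
  if (anyDuplicated(subjects$subject_id)) {
    stop("duplicate subject_id in subjects file", call. = FALSE)
  }
  subjects$subject_id <- as.character(subjects$subject_id)
  subjects$hip_fx <- as.logical(subjects$hip_fx)
  for (col in c("age_years", "fn_tscore", "ls_tscore", "fx_time_years",
                "death_time_years", "followup_years")) {
    subjects[[col]] <- as.numeric(subjects[[col]])
  }
  vert <- if (is.null(vertebrae_path)) {
    data.frame(subject_id = character(0), level = character(0),
               score = numeric(0), stringsAsFactors = FALSE)
  } else {
    read_vertebrae(vertebrae_path)
  }
  orphan <- setdiff(vert$subject_id, subjects$subject_id)
  if (length(orphan)) {
    stop("vertebra rows for unknown subject(s): ",
         paste(utils::head(orphan, 5), collapse = ", "), call. = FALSE)
  }
  structure(list(subjects = subjects, vertebrae = vert, config = NULL),
            class = "olvf_cohort")
}

#' Read and normalise a vertebrae CSV file to per-level scores
#'
#' @param path path to vertebrae.csv (see [read_cohort()] for the schema).
#' @return Data.frame `subject_id`, `level`, `score`.
#' @export
read_vertebrae <- function(path) {
  v <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "level") %in% names(v))) {
    stop("vertebrae file needs subject_id and level columns", call. = FALSE)
  }
  v$subject_id <- as.character(v$subject_id)
  line <- seq_len(nrow(v)) + 1L  # header is line 1
  bad_level <- !v$level %in% vertebral_levels()
  if (any(bad_level)) {
    stop("unknown vertebral level at line(s) ",
         paste(utils::head(line[bad_level], 5), collapse = ", "),
         ": ", paste(utils::head(unique(v$level[bad_level]), 5), collapse = ", "),
         call. = FALSE)
  }
  dup <- duplicated(v[c("subject_id", "level")])
  if (any(dup)) {
    stop("duplicate subject x level row(s) at line(s) ",
         paste(utils::head(line[dup], 5), collapse = ", "), call. = FALSE)
  }
  height_cols <- c("anterior_mm", "middle_mm", "posterior_mm")
  has_heights <- all(height_cols %in% names(v))
  has_loss <- "height_loss" %in% names(v)
  has_score <- "score" %in% names(v)
  if (has_heights && has_loss) {
    both <- !is.na(v$height_loss) & !is.na(v$anterior_mm)
    if (any(both)) {
      stop("both heights and height_loss supplied at line(s) ",
           paste(utils::head(line[both], 5), collapse = ", "), call. = FALSE)
    }
  }
  fl <- if ("fracture_like" %in% names(v)) as.logical(v$fracture_like) else TRUE
  nfc <- if ("non_fracture_cause" %in% names(v)) {
    as.logical(v$non_fracture_cause)
  } else FALSE
  fl <- rep_len(fl, nrow(v)); nfc <- rep_len(nfc, nrow(v))

  if (has_score && any(!is.na(v$score))) {
    ok <- v$score %in% c(0, -0.5, -1, -1.5, -2, -2.5, -3)
    if (any(!ok)) {
      stop("score outside {0,-0.5,...,-3} at line(s) ",
           paste(utils::head(line[!ok], 5), collapse = ", "), call. = FALSE)
    }
    score <- v$score
  } else if (has_loss && !has_heights) {
    score <- assign_esq_grade(v$height_loss, fl, nfc)$score
  } else if (has_heights) {
    score <- rep(NA_real_, nrow(v))
    for (sid in unique(v$subject_id)) {
      rows <- which(v$subject_id == sid)
      spine <- v[rows, c("level", height_cols)]
      normal <- v$level[rows][!fl[rows] & !nfc[rows]]
      for (r in rows) {
        if (!fl[r] && !nfc[r]) { score[r] <- 0; next }
        hl <- estimate_height_loss(spine, v$level[r], normal)
        score[r] <- assign_esq_grade(hl, fl[r], nfc[r])$score
      }
    }
  } else {
    stop("vertebrae file needs a score, height_loss, or height columns",
         call. = FALSE)
  }
  data.frame(subject_id = v$subject_id, level = v$level, score = score,
             stringsAsFactors = FALSE)
}

#' Score a cohort's subjects
#'
#' Builds each subject's spine assessment from the cohort's vertebra rows and
#' appends `olvfss` (adjacency-adjusted sum score), `most_severe_olvf` (raw
#' minimum score) and `n_olvf` (deformed-vertebra count) to the subjects table.
#' Subjects without vertebra rows get 0 / 0 / 0.
#'
#' @param cohort an `olvf_cohort` (from [simulate_cohort()] or [read_cohort()]).
#' @return The subjects data.frame with the three score columns appended.
#' @export
score_subjects <- function(cohort) {
  stopifnot(inherits(cohort, "olvf_cohort"))
  subjects <- cohort$subjects
  vert <- cohort$vertebrae
  m <- matrix(0, nrow(subjects), 15)
  if (nrow(vert)) {
    i <- match(vert$subject_id, subjects$subject_id)
    j <- level_index(vert$level)
    if (anyNA(i)) stop("vertebra rows for unknown subjects", call. = FALSE)
    if (anyDuplicated(cbind(i, j))) {
      stop("duplicate subject x level assessment", call. = FALSE)
    }
    if (!all(vert$score %in% c(0, -0.5, -1, -1.5, -2, -2.5, -3))) {
      stop("scores must be in {0, -0.5, -1, -1.5, -2, -2.5, -3}", call. = FALSE)
    }
    m[cbind(i, j)] <- vert$score
  }
  subjects$olvfss <- compute_olvfss(m)
  subjects$most_severe_olvf <- most_severe_olvf(m)
  subjects$n_olvf <- n_olvf(m)
  subjects
}

#' Write a cohort to subjects.csv and vertebrae.csv
#'
#' @param cohort an `olvf_cohort`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "olvf_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sp <- file.path(dir, "subjects.csv")
  vp <- file.path(dir, "vertebrae.csv")
  cols <- setdiff(names(cohort$subjects), "frailty")
  utils::write.csv(cohort$subjects[cols], sp, row.names = FALSE, na = "")
  utils::write.csv(cohort$vertebrae, vp, row.names = FALSE, na = "")
  invisible(c(subjects = sp, vertebrae = vp))
}

#' Pipeline configuration
#'
#' @param subjects,vertebrae input CSV paths (`vertebrae` may be `NULL`).
#' @param horizons follow-up horizons in years (nonempty, all positive).
#' @param out_dir output directory for `performance.csv` and `report.txt`.
#' @param metrics optional list of [metric_definition()] overrides; default:
#'   the sex's built-in set.
#' @param ppv_digits,sens_digits printed precision of PPV/incidence and
#'   sensitivity percentages in the report.
#' @return List of class `olvf_pipeline_config`.
#' @export
pipeline_config <- function(subjects, vertebrae = NULL, horizons = c(3, 5),
                            out_dir = ".", metrics = NULL,
                            ppv_digits = 3, sens_digits = 2) {
  if (length(horizons) == 0L || any(horizons <= 0)) {
    stop("horizons must be nonempty and positive", call. = FALSE)
  }
  structure(list(subjects = subjects, vertebrae = vertebrae,
                 horizons = sort(horizons), out_dir = out_dir,
                 metrics = metrics, ppv_digits = ppv_digits,
                 sens_digits = sens_digits),
            class = "olvf_pipeline_config")
}

#' Run the scoring and evaluation pipeline
#'
#' Reads (or accepts) a cohort, scores spines, and evaluates each sex
#' separately with that sex's built-in (or overridden) metrics at every
#' horizon. Writes `performance.csv` (all counts and derived percentages, plus
#' "k/n" count-pair strings) and a plain-text report, and logs row counts at
#' every stage so attrition (enrolled vs analysed) is auditable.
#'
#' @param config an [pipeline_config()], or an `olvf_cohort` to evaluate
#'   directly (then `...` passes `horizons`, `out_dir`, `metrics`).
#' @param ... overrides when `config` is a cohort.
#' @param quiet suppress progress logging.
#' @return Invisibly, the combined performance data.frame.
#' @export
run_pipeline <- function(config, ..., quiet = FALSE) {
  if (inherits(config, "olvf_cohort")) {
    cohort <- config
    args <- list(...)
    if (!"out_dir" %in% names(args)) args["out_dir"] <- list(NULL)
    config <- do.call(pipeline_config, c(list(subjects = NA_character_), args))
  } else {
    stopifnot(inherits(config, "olvf_pipeline_config"))
    cohort <- read_cohort(config$subjects, config$vertebrae)
  }
  log_ <- function(...) if (!quiet) message(sprintf(...))
  scored <- score_subjects(cohort)
  log_("read %d subjects, %d vertebra rows", nrow(scored), nrow(cohort$vertebrae))
  tables <- list()
  for (sex in intersect(c("female", "male"), unique(scored$sex))) {
    sub <- scored[scored$sex == sex, , drop = FALSE]
    metrics <- if (is.null(config$metrics)) builtin_metrics(sex) else config$metrics
    for (h in config$horizons) {
      a <- analysis_set(sub, h)
      log_("%s, horizon %g y: %d enrolled -> %d analysed (%d hip Fx)",
           sex, h, nrow(sub), nrow(a), sum(a$fx_event))
    }
    tab <- performance_table(sub, metrics, config$horizons)
    tab <- cbind(sex = sex, tab, stringsAsFactors = FALSE)
    tables[[sex]] <- tab
  }
  out <- do.call(rbind, tables)
  rownames(out) <- NULL
  out$ppv_pair <- sprintf("%d/%d", out$n_true_positive, out$n_positive)
  out$sens_pair <- sprintf("%d/%d", out$n_true_positive, out$n_fx)
  if (!is.null(config$out_dir) && !is.na(config$out_dir)) {
    if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
    utils::write.csv(out, file.path(config$out_dir, "performance.csv"),
                     row.names = FALSE, na = "")
    writeLines(render_report(out, config$ppv_digits, config$sens_digits),
               file.path(config$out_dir, "report.txt"))
  }
  invisible(out)
}

#' Render a plain-text performance report
#'
#' @param perf performance data.frame from [run_pipeline()].
#' @param ppv_digits,sens_digits printed precision (PPV and incidence / sensitivity).
#' @return Character vector of report lines.
#' @export
render_report <- function(perf, ppv_digits = 3, sens_digits = 2) {
  lines <- character(0)
  fm <- function(x, d) ifelse(is.na(x), "undefined", formatC(x, digits = d, format = "f"))
  for (sex in unique(perf$sex)) {
    for (h in unique(perf$horizon_years)) {
      p <- perf[perf$sex == sex & perf$horizon_years == h, , drop = FALSE]
      if (!nrow(p)) next
      lines <- c(lines, sprintf("== %s, %g-year follow-up ==", sex, h),
                 sprintf("analysis set: %d subjects, %d hip Fx, incidence %s%%",
                         max(p$n_analysis), max(p$n_fx),
                         fm(100 * max(p$n_fx) / max(p$n_analysis), ppv_digits)))
      for (i in seq_len(nrow(p))) {
        lines <- c(lines, sprintf(
          "  %-14s PPV %s%% (%s)  sensitivity %s%% (%s)  risk ratio %s",
          p$metric_name[i], fm(p$ppv[i], ppv_digits), p$ppv_pair[i],
          fm(p$sensitivity[i], sens_digits), p$sens_pair[i],
          fm(p$risk_ratio[i], 2)))
      }
      und <- is.na(p$sensitivity)
      if (any(und)) {
        lines <- c(lines, sprintf("  note: sensitivity undefined for %s (no events or no positives)",
                                  paste(p$metric_name[und], collapse = ", ")))
      }
      lines <- c(lines, "")
    }
  }
  lines
}

#' Write per-subject scores to subject_scores.csv
#'
#' @param scored scored subjects data.frame from [score_subjects()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_subject_scores <- function(scored, path) {
  utils::write.csv(scored[c("subject_id", "olvfss", "most_severe_olvf", "n_olvf")],
                   path, row.names = FALSE)
  invisible(path)
}
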