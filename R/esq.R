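# Extended semi-quantitative (eSQ) grading of vertebral fractural deformity.
# Severity bands refine the Genant SQ scheme into six subgrades by fractional
# vertebral height loss; each grade carries a fixed negative score.

.esq_grades <- c("none", "minimal", "mild", "moderate", "moderately_severe",
                 "severe", "collapsed")
.esq_scores <- c(none = 0, minimal = -0.5, mild = -1, moderate = -1.5,
                 moderately_severe = -2, severe = -2.5, collapsed = -3)
# left-closed bin edges for graded (>= 20%) losses; 33% and 66% are exact thirds
.esq_edges <- c(0.20, 0.25, 1 / 3, 0.40, 2 / 3)

#' eSQ grade and score table
#'
#' The fixed bijection between the seven extended semi-quantitative grades and
#' their scores, with the fractional height-loss band of each grade. Bands are
#' closed on the left and open on the right; the conventional 33% and 66% bounds are
#' exactly 1/3 and 2/3.
#'
#' @return A data.frame with columns `grade`, `score`, `loss_min`, `loss_max`.
#' @examples
#' esq_grade_table()
#' @export
esq_grade_table <- function() {
  data.frame(
    grade = .esq_grades,
    score = unname(.esq_scores),
    loss_min = c(0, 0, .esq_edges),
    loss_max = c(0, .esq_edges, 1),
    stringsAsFactors = FALSE
  )
}

#' Assign eSQ grades to vertebral findings
#'
#' Maps fractional height loss plus the two reader-judgment flags to a grade:
#'
#' * `non_fracture_cause = TRUE` (deformity attributed wholly to osteoarthritic
#'   wedging or endplatitis short vertebra) forces grade `none` whatever the loss;
#' * a loss below 20% is `minimal` (score -0.5) only when the reader judged the
#'   shape change distinctly fracture-like **and** the measured loss is positive;
#' * losses of 20% and above are graded by band regardless of `fracture_like`:
#'   \[0.20, 0.25) mild, \[0.25, 1/3) moderate, \[1/3, 0.40) moderately severe,
#'   \[0.40, 2/3) severe, \[2/3, 1\] collapsed.
#'
#' @param height_loss numeric vector of fractional height losses in \[0, 1\].
#' @param fracture_like logical vector; reader judged a distinct fracture-like
#'   morphology change (required only for the minimal grade).
#' @param non_fracture_cause logical vector; deformity wholly attributed to a
#'   non-fracture cause.
#' @return A data.frame with columns `grade` (character) and `score` (numeric),
#'   one row per finding.
#' @examples
#' assign_esq_grade(c(0.22, 0.10, 0.70), fracture_like = c(TRUE, FALSE, TRUE))
#' @export
assign_esq_grade <- function(height_loss, fracture_like = TRUE,
                             non_fracture_cause = FALSE) {
  n <- length(height_loss)
  fracture_like <- rep_len(as.logical(fracture_like), n)
  non_fracture_cause <- rep_len(as.logical(non_fracture_cause), n)
  if (anyNA(height_loss) || anyNA(fracture_like) || anyNA(non_fracture_cause)) {
    stop("missing values in vertebral findings", call. = FALSE)
  }
  if (any(height_loss < 0 | height_loss > 1)) {
    stop("height_loss must lie in [0, 1]", call. = FALSE)
  }
  # bin 1 = loss < 0.20, bins 2..6 = the graded bands (left-closed)
  bin <- findInterval(height_loss, .esq_edges) + 1L
  grade <- c("minimal", "mild", "moderate", "moderately_severe",
             "severe", "collapsed")[bin]
  grade[bin == 1L & (!fracture_like | height_loss == 0)] <- "none"
  grade[non_fracture_cause] <- "none"
  data.frame(grade = grade, score = unname(.esq_scores[grade]),
             stringsAsFactors = FALSE)
}

#' Estimate fractional vertebral height loss from morphometry
#'
#' Compares a target vertebra's anterior, middle and posterior heights with the
#' heights expected from neighbouring vertebrae of normal shape. At each height
#' position the expected height is linearly interpolated (in anatomical
#' position) between the nearest normal level above and below the target, or
#' carried over from the single nearest normal level if normal references exist
#' on one side only. The returned loss is the largest of the three positional
#' losses, floored at zero.
#'
#' @param spine data.frame with columns `level`, `anterior_mm`, `middle_mm`,
#'   `posterior_mm`; one row per measured vertebra, heights in millimetres, all
#'   positive.
#' @param target single level label whose height loss is estimated.
#' @param normal_levels character vector of levels judged morphologically
#'   normal, used as the reference; must not be empty after excluding `target`.
#' @return A single fraction in \[0, 1\].
#' @examples
#' spine <- data.frame(level = c("T11", "L1", "L2"),
#'                     anterior_mm = c(30, 20, 30),
#'                     middle_mm = c(28, 28, 28),
#'                     posterior_mm = c(29, 29, 29))
#' estimate_height_loss(spine, "L1", c("T11", "L2"))
#' @export
estimate_height_loss <- function(spine, target, normal_levels) {
  cols <- c("anterior_mm", "middle_mm", "posterior_mm")
  if (!is.data.frame(spine) || !all(c("level", cols) %in% names(spine))) {
    stop("spine must have columns level, anterior_mm, middle_mm, posterior_mm",
         call. = FALSE)
  }
  if (length(target) != 1L || !target %in% spine$level) {
    stop("target level absent from spine measurements", call. = FALSE)
  }
  h <- as.matrix(spine[cols])
  if (any(!is.finite(h)) || any(h <= 0)) {
    stop("all vertebral heights must be positive", call. = FALSE)
  }
  pos <- level_index(spine$level)
  if (anyDuplicated(pos)) stop("duplicate vertebral levels in spine", call. = FALSE)
  tpos <- level_index(target)
  ref <- setdiff(intersect(normal_levels, spine$level), target)
  if (length(ref) == 0L) {
    stop("no normal-shaped reference vertebra available", call. = FALSE)
  }
  rpos <- level_index(ref)
  rrow <- match(ref, spine$level)
  loss <- 0
  for (j in seq_along(cols)) {
    if (length(ref) == 1L) {
      expected <- h[rrow, j]
    } else {
      # approx() with rule = 2 carries the nearest value when only one side exists
      expected <- stats::approx(x = rpos, y = h[rrow, j], xout = tpos,
                                rule = 2, ties = "ordered")$y
    }
    loss <- max(loss, 1 - h[match(target, spine$level), j] / expected)
  }
  max(0, loss)
}
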