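#' Vertebral levels of the scored spine segment
#'
#' The scoring scheme covers the 15 vertebrae from T3 down to L5, in anatomical
#' order. Adjacency (used by the sum-score adjustment rules) means consecutive
#' positions in this order, so T12 and L1 are adjacent across the thoracolumbar
#' junction.
#'
#' @return Character vector of the 15 level labels, `"T3"` ... `"T12"`,
#'   `"L1"` ... `"L5"`, in anatomical order.
#' @examples
#' vertebral_levels()
#' @export
vertebral_levels <- function() {
  c(paste0("T", 3:12), paste0("L", 1:5))
}

#' Anatomical position of a vertebral level label
#'
#' @param level character vector of level labels.
#' @return Integer positions (1 = T3, ..., 15 = L5).
#' @keywords internal
level_index <- function(level) {
  idx <- match(level, vertebral_levels())
  if (anyNA(idx)) {
    bad <- unique(level[is.na(idx)])
    stop("unknown vertebral level(s) outside T3-L5: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  idx
}
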