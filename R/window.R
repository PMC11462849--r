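#' Sliding-window dot matrix
#'
#' The dotter-style comparator: for every pair of window centers the two
#' length-`window` substrings are compared position by position and a dot
#' point is emitted when the match count reaches `threshold`. Stride is
#' fixed at 1 and points are indexed by window centers, so `window` must be
#' odd. Reverse points (nucleotide only) compare A's window against the
#' reverse complement of B's window. In self mode the main diagonal is
#' suppressed and only canonical points are emitted (forward `x < y`,
#' reverse `x <= y`; a window may pair with its own reverse complement).
#'
#' @param seqA A [seq_record()] (or residue string).
#' @param seqB Optional second sequence; omitted or identical to `seqA`
#'   means self mode.
#' @param window Odd window size. Default 11.
#' @param threshold Minimum match count in a window. Default 7.
#' @param search_reverse Also emit reverse-complement points (forced off for
#'   proteins).
#' @return A data frame `x, y, score, orientation` sorted by
#'   `(orientation, x, y)`; `x` and `y` are 1-based window-center positions.
#' @export
sliding_window_dotmatrix <- function(seqA, seqB = NULL, window = 11L,
                                     threshold = 7L, search_reverse = TRUE) {
  seqA <- as_seq_record(seqA, id = "seqA")
  self_mode <- is.null(seqB)
  if (!self_mode) {
    seqB <- as_seq_record(seqB, id = "seqB")
    if (seqA$alphabet != seqB$alphabet)
      stop("alphabet mismatch: ", seqA$alphabet, " vs ", seqB$alphabet)
    if (identical(seqA$residues, seqB$residues) &&
        identical(seqA$id, seqB$id)) self_mode <- TRUE
  } else {
    seqB <- seqA
  }
  window <- as.integer(window)
  threshold <- as.integer(threshold)
  if (window %% 2L == 0L)
    stop("'window' must be odd so that window centers are well-defined")
  stopifnot(window >= 1L, threshold >= 1L, threshold <= window,
            window <= min(seqA$length, seqB$length))
  if (seqA$alphabet == "protein") search_reverse <- FALSE
  pts <- cpp_window_dotmatrix(seqA$residues, seqB$residues,
                              seqA$alphabet == "nucleotide",
                              window, threshold,
                              isTRUE(search_reverse), self_mode)
  ord <- order(match(pts$orientation, c("forward", "reverse")), pts$x, pts$y)
  pts <- pts[ord, , drop = FALSE]
  rownames(pts) <- NULL
  pts
}
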