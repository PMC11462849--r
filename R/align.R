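#' Alignment and filtering parameters for repeat extraction
#'
#' Scoring is identity-based for both nucleotide and protein sequences:
#' `match_score` for identical unambiguous residues, `mismatch_score`
#' otherwise. Ambiguity codes (`N` and friends; `X`, `B`, `Z`, `*` for
#' proteins) score as mismatches against everything, including themselves,
#' giving conservative identity estimates. Gaps are affine: a gap of length
#' k costs `gap_open + (k - 1) * gap_extend`.
#'
#' `min_length` counts alignment columns (gaps included), so one threshold
#' governs both intervals of a pair. `search_reverse = NULL` resolves by
#' alphabet at call time: reverse-complement search is on for nucleotide
#' sequences and forced off for proteins.
#'
#' @param match_score Score for a residue match (> 0). Default 1.
#' @param mismatch_score Score for a mismatch (<= 0). Default -1.
#' @param gap_open Score for opening a gap (<= gap_extend). Default -4.
#' @param gap_extend Score for extending a gap (<= 0). Default -2. Gap
#'   extension cheaper than a mismatch lets chance gapped alignments
#'   accrete in random DNA; the stiffer default keeps repeat boundaries
#'   crisp and costs nothing for substitution-diverged repeats.
#' @param min_length Minimum alignment columns for a reported pair. Default 30.
#' @param min_identity Minimum identity (matches / columns) in `[0, 1]`.
#'   Default 0.45.
#' @param min_score Minimum alignment score. Default 15.
#' @param max_pairs Cap on reported pairs per comparison. Default 10000.
#' @param search_reverse `TRUE`, `FALSE`, or `NULL` (resolve by alphabet).
#' @param trim_identity End-trim level in `[0, 1]`; 0 disables. After
#'   traceback, the alignment is cut to the maximum-sum subarray of its
#'   per-column scores shifted by the mean column score at this identity
#'   level. This strips chance end-extensions of the local alignment into
#'   the flanking sequence (which otherwise blur reported repeat
#'   boundaries) while leaving any core above the trim level intact.
#'   Repeats whose overall identity is below the trim level may be
#'   truncated or dropped, so keep it modest; default 0.55, just above the
#'   effective identity of gapped chance alignment of random DNA.
#' @return An object of class `align_params`.
#' @export
align_params <- function(match_score = 1, mismatch_score = -1,
                         gap_open = -4, gap_extend = -2,
                         min_length = 30L, min_identity = 0.45,
                         min_score = 15, max_pairs = 10000L,
                         search_reverse = NULL, trim_identity = 0.55) {
  stopifnot(match_score > 0, mismatch_score <= 0,
            gap_open <= gap_extend, gap_extend <= 0,
            min_identity >= 0, min_identity <= 1,
            trim_identity >= 0, trim_identity <= 1,
            min_length >= 1, max_pairs >= 1)
  structure(
    list(match_score = match_score, mismatch_score = mismatch_score,
         gap_open = gap_open, gap_extend = gap_extend,
         min_length = as.integer(min_length), min_identity = min_identity,
         min_score = min_score, max_pairs = as.integer(max_pairs),
         search_reverse = search_reverse, trim_identity = trim_identity),
    class = "align_params")
}

#' @export
print.align_params <- function(x, ...) {
  cat("align_params:",
      sprintf("match %+g, mismatch %+g, gap %+g/%+g,", x$match_score,
              x$mismatch_score, x$gap_open, x$gap_extend),
      sprintf("min_length %d, min_identity %.2f, min_score %g",
              x$min_length, x$min_identity, x$min_score), "\n")
  invisible(x)
}

resolve_reverse <- function(params, alphabet) {
  if (alphabet == "protein") return(FALSE)
  if (is.null(params$search_reverse)) TRUE else isTRUE(params$search_reverse)
}

MAX_DP_LENGTH <- 50000L

check_dp_length <- function(...) {
  for (L in list(...)) {
    if (L > MAX_DP_LENGTH)
      stop("sequence of length ", L, " exceeds the ", MAX_DP_LENGTH,
           " residue limit of the O(L^2) aligner; for longer inputs use ",
           "sliding_window_dotmatrix()")
  }
}

#' Best local alignment of two residue strings
#'
#' Smith-Waterman local alignment with affine gaps (Gotoh). Returns the
#' single maximum-scoring local alignment; when no cell scores above zero
#' the alignment is empty (score 0, zero-length spans).
#'
#' @param a,b Residue strings or [seq_record()] objects of the same alphabet.
#' @param params An [align_params()] object (thresholds are ignored here;
#'   only the scoring fields are used).
#' @return A list with `score`, `aligned_a`, `aligned_b`, `a_start`,
#'   `a_end`, `b_start`, `b_end`, `matches`, `columns`, `identity`.
#' @examples
#' local_align("ACGT", "ACCT")
#' @export
local_align <- function(a, b, params = align_params()) {
  a <- as_seq_record(a, id = "a")
  b <- as_seq_record(b, id = "b")
  if (a$alphabet != b$alphabet)
    stop("alphabet mismatch: ", a$alphabet, " vs ", b$alphabet)
  check_dp_length(a$length, b$length)
  res <- cpp_extract_all(a$residues, b$residues,
                         a$alphabet == "nucleotide",
                         params$match_score, params$mismatch_score,
                         params$gap_open, params$gap_extend,
                         1L, 0, 1e-9, 1L, 0L, 0)
  if (length(res$score) == 0L)
    return(list(score = 0, aligned_a = "", aligned_b = "",
                a_start = 0L, a_end = -1L, b_start = 0L, b_end = -1L,
                matches = 0L, columns = 0L, identity = NA_real_))
  list(score = res$score[1L],
       aligned_a = res$aligned_a[1L], aligned_b = res$aligned_b[1L],
       a_start = res$a_start[1L], a_end = res$a_end[1L],
       b_start = res$b_start[1L], b_end = res$b_end[1L],
       matches = res$matches[1L], columns = res$columns[1L],
       identity = res$matches[1L] / res$columns[1L])
}

pairs_from_cpp <- function(res, id1, id2, orientation, map_b_len = NULL) {
  n <- length(res$score)
  if (n == 0L) return(repeat_pairs_df())
  b_start <- res$b_start
  b_end <- res$b_end
  if (!is.null(map_b_len)) {       # intervals reported in revcomp coordinates
    s2 <- map_b_len - b_end + 1L
    e2 <- map_b_len - b_start + 1L
    b_start <- s2
    b_end <- e2
  }
  repeat_pairs_df(rep(id1, n), rep(id2, n),
                  res$a_start, res$a_end, b_start, b_end,
                  rep(orientation, n),
                  res$matches, res$columns,
                  res$matches / res$columns, res$score,
                  res$aligned_a, res$aligned_b)
}

run_extract <- function(a_res, b_res, nucleotide, params, mode) {
  ti <- params$trim_identity
  tau <- if (is.null(ti) || ti <= 0) 0
         else ti * params$match_score + (1 - ti) * params$mismatch_score
  cpp_extract_all(a_res, b_res, nucleotide,
                  params$match_score, params$mismatch_score,
                  params$gap_open, params$gap_extend,
                  params$min_length, params$min_identity,
                  params$min_score, params$max_pairs, mode, tau)
}

#' Find all repeat pairs within one sequence
#'
#' Iterated Smith-Waterman self-comparison: repeatedly finds the best
#' remaining local alignment, records it when it passes the thresholds in
#' `params`, masks the cells on its alignment path (plus a 1-cell
#' neighborhood) and searches again, until nothing scores `min_score` or
#' `max_pairs` is reached. Residues are never masked, so a residue can take
#' part in many pairs. Forward pairs come from the self-matrix with the
#' near-diagonal band `|i - j| < min_length` forbidden (this excludes the
#' trivial self-match and canonicalizes `start1 < start2`); reverse pairs
#' (nucleotide only) from the sequence against its reverse complement, with
#' the first copy required to precede the second on the forward strand.
#' Both intervals of a reverse pair are reported on the forward strand.
#'
#' @param seq A [seq_record()] (or residue string).
#' @param params An [align_params()] object.
#' @return A `repeat_pairs` data frame sorted by `(start1, start2,
#'   orientation)`. A sequence shorter than `2 * min_length` yields an empty
#'   table with a warning.
#' @examples
#' p <- find_self_repeats(seq_record("g", "AAGGCTTTTTAAGGCT"),
#'                        align_params(min_length = 4, min_score = 4))
#' @export
find_self_repeats <- function(seq, params = align_params()) {
  seq <- as_seq_record(seq)
  if (seq$length < 2L * params$min_length) {
    warning("sequence '", seq$id, "' is shorter than 2*min_length (",
            seq$length, " < ", 2L * params$min_length,
            "); no repeat search performed")
    return(repeat_pairs_df())
  }
  check_dp_length(seq$length)
  nuc <- seq$alphabet == "nucleotide"
  fwd <- run_extract(seq$residues, seq$residues, nuc, params, 1L)
  if (isTRUE(fwd$truncated))
    warning("max_pairs reached on '", seq$id, "'; pair list truncated")
  pairs <- pairs_from_cpp(fwd, seq$id, seq$id, "forward")
  if (resolve_reverse(params, seq$alphabet)) {
    rev <- run_extract(seq$residues, revcomp(seq$residues), nuc, params, 2L)
    if (isTRUE(rev$truncated))
      warning("max_pairs reached on '", seq$id,
              "' (reverse); pair list truncated")
    pairs <- rbind(pairs,
                   pairs_from_cpp(rev, seq$id, seq$id, "reverse",
                                  map_b_len = seq$length))
  }
  sort_pairs(pairs)
}

#' Find all repeat pairs between two sequences
#'
#' Same iterated local-alignment engine as [find_self_repeats()], applied to
#' two different sequences; no cells are forbidden and no canonicalization
#' constraint applies. With reverse search on (nucleotide only), sequence A
#' is additionally compared against the reverse complement of B; reverse
#' pairs report interval2 on B's forward strand.
#'
#' @param seqA,seqB [seq_record()] objects (or residue strings) of the same
#'   alphabet.
#' @param params An [align_params()] object.
#' @return A `repeat_pairs` data frame sorted by `(start1, start2,
#'   orientation)`.
#' @export
find_cross_repeats <- function(seqA, seqB, params = align_params()) {
  seqA <- as_seq_record(seqA, id = "seqA")
  seqB <- as_seq_record(seqB, id = "seqB")
  if (seqA$alphabet != seqB$alphabet)
    stop("alphabet mismatch: ", seqA$alphabet, " vs ", seqB$alphabet)
  check_dp_length(seqA$length, seqB$length)
  nuc <- seqA$alphabet == "nucleotide"
  fwd <- run_extract(seqA$residues, seqB$residues, nuc, params, 0L)
  if (isTRUE(fwd$truncated))
    warning("max_pairs reached; pair list truncated")
  pairs <- pairs_from_cpp(fwd, seqA$id, seqB$id, "forward")
  if (resolve_reverse(params, seqA$alphabet)) {
    rev <- run_extract(seqA$residues, revcomp(seqB$residues), nuc, params, 0L)
    if (isTRUE(rev$truncated))
      warning("max_pairs reached (reverse); pair list truncated")
    pairs <- rbind(pairs,
                   pairs_from_cpp(rev, seqA$id, seqB$id, "reverse",
                                  map_b_len = seqB$length))
  }
  sort_pairs(pairs)
}

#' Extract all repeat pairs (dispatcher)
#'
#' Thin front end over [find_self_repeats()] (one sequence) and
#' [find_cross_repeats()] (two sequences).
#'
#' @param seq First sequence.
#' @param seq2 Optional second sequence for cross-comparison.
#' @param params An [align_params()] object.
#' @return A `repeat_pairs` data frame.
#' @export
extract_all <- function(seq, seq2 = NULL, params = align_params()) {
  if (is.null(seq2)) find_self_repeats(seq, params)
  else find_cross_repeats(seq, seq2, params)
}

#' Filter repeat pairs to long intragenic repeats (LIRs)
#'
#' Keeps pairs whose alignment spans at least `min_length` columns. The
#' length threshold defining a "long" repeat is a user decision; 100 aligned
#' columns is the default here.
#'
#' @param pairs A `repeat_pairs` data frame.
#' @param min_length Minimum aligned columns. Default 100.
#' @return The filtered `repeat_pairs` data frame.
#' @export
filter_lir <- function(pairs, min_length = 100L) {
  out <- pairs[pairs$aln_columns >= min_length, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Recompute the score of repeat pairs from their aligned strings
#'
#' Self-consistency helper: scores each pair's stored alignment under
#' `params` (match/mismatch per column, affine gap runs).
#'
#' @param pairs A `repeat_pairs` data frame.
#' @param params An [align_params()] object.
#' @param nucleotide Whether residues are nucleotide (for ambiguity rules).
#' @return Numeric vector of recomputed scores.
#' @export
rescore_pairs <- function(pairs, params = align_params(), nucleotide = TRUE) {
  vapply(seq_len(nrow(pairs)), function(k) {
    s1 <- strsplit(pairs$aligned_seq1[k], "", fixed = TRUE)[[1L]]
    s2 <- strsplit(pairs$aligned_seq2[k], "", fixed = TRUE)[[1L]]
    score <- 0
    gap_side <- 0L   # 1 = gap in seq1, 2 = gap in seq2; switching reopens
    for (i in seq_along(s1)) {
      if (s1[i] == "-" || s2[i] == "-") {
        side <- if (s1[i] == "-") 1L else 2L
        score <- score +
          if (gap_side == side) params$gap_extend else params$gap_open
        gap_side <- side
      } else {
        gap_side <- 0L
        ok <- res_match_r(s1[i], s2[i], nucleotide)
        score <- score + if (ok) params$match_score else params$mismatch_score
      }
    }
    score
  }, numeric(1))
}

## R-side mirror of the C++ residue matching rule
res_match_r <- function(x, y, nucleotide) {
  if (nucleotide) {
    unamb <- c("A", "C", "G", "T", "U")
    if (!(x %in% unamb) || !(y %in% unamb)) return(FALSE)
    chartr("U", "T", x) == chartr("U", "T", y)
  } else {
    !(x %in% c("X", "B", "Z", "*")) && x == y
  }
}
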