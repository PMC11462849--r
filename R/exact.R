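exact_repeats_df <- function(seq_id, df) {
  out <- data.frame(seq_id = rep(seq_id, nrow(df)),
                    start1 = as.integer(df$start1),
                    start2 = as.integer(df$start2),
                    length = as.integer(df$length),
                    orientation = as.character(df$orientation),
                    stringsAsFactors = FALSE)
  ord <- order(out$start1, out$start2,
               match(out$orientation, c("forward", "reverse")))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("exact_repeats", "data.frame")
  out
}

#' Find all maximal exact repeats of a sequence
#'
#' The repeat-match role: every pair of identical (or, with
#' `search_reverse`, reverse-complementary) substrings of length at least
#' `min_length` that cannot be extended on either side. Overlapping copies
#' (`start2 - start1 < length`, e.g. in homopolymer runs) are reported.
#' A reverse-complement palindrome is split at its center into two disjoint
#' copies; reverse pairs always have the first copy strictly before the
#' second on the forward strand. Ambiguity codes (`N` etc.) never match,
#' including against themselves.
#'
#' @param seq A [seq_record()] (or residue string).
#' @param min_length Minimum repeat length (>= 2).
#' @param search_reverse Also search reverse-complement repeats (nucleotide
#'   sequences only; forced off for proteins).
#' @return A data frame `seq_id, start1, start2, length, orientation`
#'   sorted by `(start1, start2, orientation)`; 1-based coordinates.
#' @examples
#' find_maximal_exact_repeats(seq_record("g", "AAGGCTQRSWVPAAGGCT",
#'                                       alphabet = "protein"),
#'                            min_length = 4, search_reverse = FALSE)
#' @export
find_maximal_exact_repeats <- function(seq, min_length = 30L,
                                       search_reverse = TRUE) {
  seq <- as_seq_record(seq)
  stopifnot(min_length >= 2)
  if (seq$alphabet == "protein") search_reverse <- FALSE
  df <- cpp_exact_repeats(seq$residues, seq$alphabet == "nucleotide",
                          as.integer(min_length), isTRUE(search_reverse))
  exact_repeats_df(seq$id, df)
}

#' Brute-force maximal exact repeats (test oracle)
#'
#' Direct enumeration: every position pair is tested for a match that is not
#' the continuation of a match one step back, then extended outward to
#' maximal length, under exactly the same reporting policy as
#' [find_maximal_exact_repeats()] (overlaps reported, palindromes split at
#' their center, ambiguity codes never match). Cubic-ish and intended only
#' for test-scale sequences.
#'
#' @inheritParams find_maximal_exact_repeats
#' @return Same contract as [find_maximal_exact_repeats()].
#' @export
brute_force_exact_repeats <- function(seq, min_length = 30L,
                                      search_reverse = TRUE) {
  seq <- as_seq_record(seq)
  stopifnot(min_length >= 2)
  m <- seq$length
  if (m > 2000L) stop("brute-force oracle limited to sequences <= 2000")
  if (seq$alphabet == "protein") search_reverse <- FALSE
  nuc <- seq$alphabet == "nucleotide"
  ch <- strsplit(seq$residues, "", fixed = TRUE)[[1L]]
  mt <- function(i, j) {
    if (i < 1L || j < 1L || i > m || j > m) return(FALSE)
    res_match_r(ch[i], ch[j], nuc)
  }
  s1 <- integer(); s2 <- integer(); len <- integer(); ori <- character()

  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (j <= i) next
      if (!mt(i, j) || mt(i - 1L, j - 1L)) next    # not a run start
      k <- 0L
      while (mt(i + k + 1L, j + k + 1L)) k <- k + 1L
      if (k + 1L >= min_length) {
        s1 <- c(s1, i); s2 <- c(s2, j); len <- c(len, k + 1L)
        ori <- c(ori, "forward")
      }
    }
  }

  if (search_reverse) {
    cmp <- strsplit(revcomp(seq$residues), "", fixed = TRUE)[[1L]]
    # M[i, p]: position i matches the complement of position p
    mtr <- function(i, p) {
      if (i < 1L || p < 1L || i > m || p > m) return(FALSE)
      res_match_r(ch[i], cmp[m - p + 1L], nuc)
    }
    for (i in seq_len(m)) {
      for (p in seq_len(m)) {
        if (!mtr(i, p) || mtr(i - 1L, p + 1L)) next  # not a run start
        k <- 0L
        while (mtr(i + k + 1L, p - k - 1L)) k <- k + 1L
        run_len <- k + 1L
        if (i >= p) next                              # mirror representation
        kept <- min(run_len, ceiling((p - i) / 2))    # keep cells with i' < p'
        if (kept >= min_length) {
          s1 <- c(s1, i); s2 <- c(s2, p - kept + 1L)
          len <- c(len, kept); ori <- c(ori, "reverse")
        }
      }
    }
  }

  exact_repeats_df(seq$id,
                   data.frame(start1 = s1, start2 = s2, length = len,
                              orientation = ori, stringsAsFactors = FALSE))
}
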