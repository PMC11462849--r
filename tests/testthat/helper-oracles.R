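# Shared test fixtures and independent oracles. Fixtures are built in code;
# oracles are implemented independently of the code paths they check.

# Jaccard overlap of two 1-based inclusive intervals
jaccard <- function(a, b) {
  inter <- max(0L, min(a[2], b[2]) - max(a[1], b[1]) + 1L)
  union <- (a[2] - a[1] + 1L) + (b[2] - b[1] + 1L) - inter
  inter / union
}

# Independent local-alignment score oracle: Biostrings pairwiseAlignment.
# Gap-cost mapping: intrarep charges gap_open for the first gap column and
# gap_extend for each further one; Biostrings charges gapOpening once plus
# gapExtension per column.
oracle_local_score <- function(a, b, params = align_params()) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = params$match_score, mismatch = params$mismatch_score,
    baseOnly = TRUE)
  Biostrings::pairwiseAlignment(
    a, b, type = "local", substitutionMatrix = mat,
    gapOpening = -(params$gap_open - params$gap_extend),
    gapExtension = -params$gap_extend, scoreOnly = TRUE)
}

# Direct enumeration oracle for the sliding-window dot matrix (self mode)
oracle_window_points <- function(s, window, threshold) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  L <- length(ch)
  h <- (window - 1) / 2
  rc <- strsplit(revcomp(s), "", fixed = TRUE)[[1]]
  rows <- list()
  for (i in (h + 1):(L - h)) {
    for (j in (h + 1):(L - h)) {
      if (j > i) {
        sc <- sum(ch[(i - h):(i + h)] == ch[(j - h):(j + h)])
        if (sc >= threshold)
          rows[[length(rows) + 1]] <-
            data.frame(x = i, y = j, score = sc, orientation = "forward")
      }
      if (j >= i) {
        # revcomp of the window centered at j, read left to right
        win_rc <- rev(vapply((j - h):(j + h), function(p)
          chartr("ACGT", "TGCA", ch[p]), character(1)))
        sc <- sum(ch[(i - h):(i + h)] == win_rc)
        if (sc >= threshold)
          rows[[length(rows) + 1]] <-
            data.frame(x = i, y = j, score = sc, orientation = "reverse")
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(match(out$orientation, c("forward", "reverse")),
                   out$x, out$y), ]
  rownames(out) <- NULL
  out
}

# Plant one two-copy duplication of the given unit length and divergence in
# a fresh random background.
plant_one_dup <- function(seed, L = 1000L, unit = 200L, divergence = 0) {
  bg <- random_sequence(L, seed = seed)
  plant_repeats(bg, unit_length = unit, n_copies = 2L,
                divergence = divergence,
                positions = c(round(L * 0.15), round(L * 0.6)),
                seed = seed + 5000L)
}

# Plant three separate two-copy duplications (one per length/divergence) in
# non-overlapping thirds of a length-2000 background. Lengths in [50, 200]
# derived arithmetically from the seed so they vary across seeds.
plant_three_dups <- function(seed, divs = c(0, 0.1, 0.3)) {
  s <- random_sequence(2000L, seed = seed)
  slot_lo <- c(1L, 667L, 1334L)
  truths <- list()
  for (k in 1:3) {
    len <- 50L + ((seed * 37L + k * 61L) %% 151L)
    p1 <- slot_lo[k] + 5L
    p2 <- p1 + len + 30L
    pl <- plant_repeats(s, unit_length = len, n_copies = 2L,
                        divergence = divs[k], positions = c(p1, p2),
                        seed = seed * 10L + k)
    s <- pl$sequence
    truths[[k]] <- pl$truth
  }
  list(sequence = s, truth = do.call(rbind, truths))
}

# Is a dpfinder pair contained (both intervals, same orientation) inside
# some maximal exact repeat of the given table?
pair_in_exact <- function(pair, exact) {
  hits <- exact[exact$orientation == pair$orientation, , drop = FALSE]
  if (!nrow(hits)) return(FALSE)
  any(hits$start1 <= pair$start1 &
      hits$start1 + hits$length - 1L >= pair$end1 &
      hits$start2 <= pair$start2 &
      hits$start2 + hits$length - 1L >= pair$end2)
}

# Welch t statistic and two-sided p computed directly from the formula
oracle_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}

withr_local_tempfile <- function() tempfile()

# build a minimal valid repeat_pairs row for stats/io tests
make_pair <- function(start1, end1, start2, end2, orientation = "forward",
                      identity = 1, id = "seq") {
  n1 <- end1 - start1 + 1L
  aln <- strrep("A", n1)
  intrarep:::repeat_pairs_df(id, id, start1, end1, start2, end2, orientation,
                             matches = round(identity * n1), aln_columns = n1,
                             identity = identity, score = n1,
                             aligned_seq1 = aln, aligned_seq2 = aln)
}

sort_by_start <- function(pairs) {
  ord <- order(pairs$start1, pairs$start2,
               match(pairs$orientation, c("forward", "reverse")))
  out <- pairs[ord, ]
  rownames(out) <- NULL
  out
}
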