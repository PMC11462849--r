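#' Read a FASTA file into sequence records
#'
#' Line wrapping and blank lines are tolerated. Residues are uppercased.
#' Record ids are the header token up to the first whitespace and must be
#' unique within the file; empty files, empty sequences, and residues that
#' are illegal for the declared alphabet are errors.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"auto"` (default), `"nucleotide"` or `"protein"`.
#'   Auto-detection calls a record nucleotide when >= 90% of residues are in
#'   `A,C,G,T,U,N`.
#' @return A list of [seq_record()] objects.
#' @export
read_fasta <- function(path, alphabet = c("auto", "nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) stop("FASTA record with empty id in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA id '", dup[1L], "' in ", path)
  recs <- lapply(seq_along(set), function(k)
    seq_record(ids[k], as.character(set[[k]]), alphabet))
  names(recs) <- ids
  recs
}

#' Write sequence records to a FASTA file
#'
#' @param records A list of [seq_record()] objects (or a single one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "seq_record")) records <- list(records)
  seqs <- vapply(records, function(r) r$residues, character(1))
  ids <- vapply(records, function(r) r$id, character(1))
  set <- Biostrings::BStringSet(seqs)
  names(set) <- ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

## internal constructor for the repeat-pair table shared by dpfinder and io
repeat_pairs_df <- function(seq_id_1 = character(), seq_id_2 = character(),
                            start1 = integer(), end1 = integer(),
                            start2 = integer(), end2 = integer(),
                            orientation = character(),
                            matches = integer(), aln_columns = integer(),
                            identity = numeric(), score = numeric(),
                            aligned_seq1 = character(),
                            aligned_seq2 = character()) {
  df <- data.frame(
    seq_id_1 = seq_id_1, seq_id_2 = seq_id_2,
    start1 = as.integer(start1), end1 = as.integer(end1),
    start2 = as.integer(start2), end2 = as.integer(end2),
    orientation = orientation,
    length1 = as.integer(end1) - as.integer(start1) + 1L,
    length2 = as.integer(end2) - as.integer(start2) + 1L,
    matches = as.integer(matches), aln_columns = as.integer(aln_columns),
    identity = identity, score = score,
    aligned_seq1 = aligned_seq1, aligned_seq2 = aligned_seq2,
    stringsAsFactors = FALSE)
  class(df) <- c("repeat_pairs", "data.frame")
  df
}

sort_pairs <- function(pairs) {
  ord <- order(pairs$start1, pairs$start2,
               match(pairs$orientation, c("forward", "reverse")))
  pairs <- pairs[ord, , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Write a repeat-pair table to TSV
#'
#' Columns, in order: `seq_id, start1, end1, start2, end2, orientation,
#' length1, length2, matches, aln_columns, identity, score, aligned_seq1,
#' aligned_seq2`. Rows are sorted by `(start1, start2, orientation)`;
#' identity and score are printed with 4 decimal places. Coordinates are
#' 1-based inclusive on the forward strand; for reverse pairs the second
#' interval's residues align after reverse-complementation. For cross-
#' sequence pairs with differing ids, `seq_id` is written as `"id1|id2"`.
#'
#' @param pairs A `repeat_pairs` table from [find_self_repeats()] or
#'   [find_cross_repeats()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_repeats_tsv <- function(pairs, path) {
  pairs <- sort_pairs(pairs)
  seq_id <- ifelse(pairs$seq_id_1 == pairs$seq_id_2, pairs$seq_id_1,
                   paste0(pairs$seq_id_1, "|", pairs$seq_id_2))
  out <- data.frame(
    seq_id = seq_id,
    start1 = pairs$start1, end1 = pairs$end1,
    start2 = pairs$start2, end2 = pairs$end2,
    orientation = pairs$orientation,
    length1 = pairs$length1, length2 = pairs$length2,
    matches = pairs$matches, aln_columns = pairs$aln_columns,
    identity = sprintf("%.4f", pairs$identity),
    score = sprintf("%.4f", pairs$score),
    aligned_seq1 = pairs$aligned_seq1, aligned_seq2 = pairs$aligned_seq2,
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a repeat-pair table written by [write_repeats_tsv()]
#'
#' @param path Path to the TSV file.
#' @return A `repeat_pairs` table.
#' @export
read_repeats_tsv <- function(path) {
  raw <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(aligned_seq1 = "character",
                                   aligned_seq2 = "character"))
  id1 <- sub("\\|.*$", "", raw$seq_id)
  id2 <- sub("^[^|]*\\|?", "", raw$seq_id)
  id2 <- ifelse(nzchar(id2), id2, id1)
  repeat_pairs_df(id1, id2, raw$start1, raw$end1, raw$start2, raw$end2,
                  raw$orientation, raw$matches, raw$aln_columns,
                  raw$identity, raw$score,
                  raw$aligned_seq1, raw$aligned_seq2)
}

#' Write dot-plot segment coordinates for repeat pairs
#'
#' One segment per aligned pair, columns `x1, y1, x2, y2, orientation,
#' identity`. Forward pairs run with positive slope (`(start1,start2)` to
#' `(end1,end2)`); reverse pairs with negative slope (`(start1,end2)` to
#' `(end1,start2)`).
#'
#' @inheritParams write_repeats_tsv
#' @return `path`, invisibly.
#' @export
write_dot_coordinates <- function(pairs, path) {
  pairs <- sort_pairs(pairs)
  fwd <- pairs$orientation == "forward"
  out <- data.frame(
    x1 = pairs$start1,
    y1 = ifelse(fwd, pairs$start2, pairs$end2),
    x2 = pairs$end1,
    y2 = ifelse(fwd, pairs$end2, pairs$start2),
    orientation = pairs$orientation,
    identity = sprintf("%.4f", pairs$identity),
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
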