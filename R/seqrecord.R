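NUC_CHARS <- c("A", "C", "G", "T", "U", "N",
               "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
PROT_CHARS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                "P", "Q", "R", "S", "T", "V", "W", "Y", "X", "*", "B", "Z",
                "U")

#' Construct a sequence record
#'
#' A `seq_record` holds one identified biological sequence with a declared
#' alphabet. Residues are uppercased; illegal residues for the declared
#' alphabet are an error. With `alphabet = "auto"`, the sequence is called
#' nucleotide when at least 90% of its residues are in `A,C,G,T,U,N`,
#' protein otherwise.
#'
#' @param id Non-empty identifier (FASTA header token up to first space).
#' @param residues Character scalar of residues.
#' @param alphabet `"auto"`, `"nucleotide"` or `"protein"`.
#' @return An object of class `seq_record` with fields `id`, `residues`,
#'   `alphabet`, `length`.
#' @examples
#' seq_record("g1", "acgtACGT")
#' @export
seq_record <- function(id, residues, alphabet = c("auto", "nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id))
    stop("'id' must be a non-empty string")
  if (!is.character(residues) || length(residues) != 1L || is.na(residues))
    stop("'residues' must be a character scalar")
  residues <- toupper(residues)
  if (!nzchar(residues))
    stop("record '", id, "' has an empty sequence")
  if (alphabet == "auto") alphabet <- detect_alphabet(residues)
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  legal <- if (alphabet == "nucleotide") NUC_CHARS else PROT_CHARS
  bad <- which(!(chars %in% legal))
  if (length(bad))
    stop("record '", id, "': illegal ", alphabet, " residue '",
         chars[bad[1L]], "' at position ", bad[1L])
  structure(
    list(id = id, residues = residues, alphabet = alphabet,
         length = nchar(residues)),
    class = "seq_record")
}

detect_alphabet <- function(residues) {
  chars <- strsplit(toupper(residues), "", fixed = TRUE)[[1L]]
  frac <- mean(chars %in% c("A", "C", "G", "T", "U", "N"))
  if (frac >= 0.9) "nucleotide" else "protein"
}

#' @export
print.seq_record <- function(x, ...) {
  prev <- if (x$length > 60L) paste0(substr(x$residues, 1L, 57L), "...")
          else x$residues
  cat(sprintf("seq_record '%s' (%s, %d residues)\n  %s\n",
              x$id, x$alphabet, x$length, prev))
  invisible(x)
}

as_seq_record <- function(x, alphabet = "auto", id = "seq") {
  if (inherits(x, "seq_record")) return(x)
  if (is.character(x) && length(x) == 1L) return(seq_record(id, x, alphabet))
  stop("expected a seq_record or a single character string")
}

#' Reverse complement of a nucleotide string
#'
#' IUPAC ambiguity codes are complemented to their partners; `U` complements
#' to `A`.
#'
#' @param x Character scalar (or `seq_record`) of nucleotide residues.
#' @return Character scalar, the reverse complement.
#' @examples
#' revcomp("AAGG") # "CCTT"
#' @export
revcomp <- function(x) {
  if (inherits(x, "seq_record")) {
    if (x$alphabet != "nucleotide")
      stop("reverse complement is defined for nucleotide sequences only")
    x <- x$residues
  }
  cpp_revcomp(toupper(x))
}
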