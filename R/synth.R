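## run expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

NUC_CORE <- c("A", "C", "G", "T")
PROT_CORE <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
               "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Random sequence with i.i.d. uniform residues
#'
#' @param length Sequence length (>= 1).
#' @param alphabet `"nucleotide"` (ACGT) or `"protein"` (20 amino acids).
#' @param seed Integer seed; identical seeds give identical sequences.
#' @param id Record id. Default encodes length and seed.
#' @return A [seq_record()].
#' @export
random_sequence <- function(length, alphabet = c("nucleotide", "protein"),
                            seed = 1L, id = NULL) {
  alphabet <- match.arg(alphabet)
  length <- as.integer(length)
  if (is.na(length) || length < 1L) stop("'length' must be >= 1")
  if (is.null(id)) id <- sprintf("rand_%s_L%d_s%d",
                                 substr(alphabet, 1, 3), length, seed)
  pool <- if (alphabet == "nucleotide") NUC_CORE else PROT_CORE
  res <- with_seed(seed,
    paste(sample(pool, length, replace = TRUE), collapse = ""))
  seq_record(id, res, alphabet)
}

## substitutions that always change the residue, per-position prob `rate`
mutate_subs <- function(chars, rate, pool) {
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    alt <- setdiff(pool, chars[i])
    chars[i] <- alt[sample.int(length(alt), 1L)]
  }
  chars
}

## simple indels: per-position deletion or single-residue insertion,
## each with prob indel_rate / 2
mutate_indels <- function(chars, indel_rate, pool) {
  out <- character(0)
  for (i in seq_along(chars)) {
    u <- stats::runif(1L)
    if (u < indel_rate / 2) next                       # deletion
    if (u < indel_rate) out <- c(out, pool[sample.int(length(pool), 1L)])
    out <- c(out, chars[i])
  }
  out
}

#' Plant repeat copies of controlled divergence into a background sequence
#'
#' A template unit is drawn at random; copy 1 is the template verbatim and
#' every further copy is an independently mutated version (per-position
#' substitution probability `divergence`; substitutions always change the
#' residue, so the expected realized divergence equals the nominal one).
#' Copies are written into the background by overwriting (fixed total
#' length, stable coordinates); a reverse-oriented copy is written as the
#' reverse complement of its mutated unit. The returned truth table lists
#' every copy pair with its realized identity computed by direct comparison
#' of the mutated units (or by global alignment when indels are enabled).
#'
#' @param background A [seq_record()] to plant into.
#' @param unit_length Length of the repeat unit.
#' @param n_copies Number of copies (>= 2).
#' @param divergence Per-position substitution probability in `[0, 1)`
#'   applied to each non-template copy.
#' @param orientation_of_copies Character vector (`"forward"`/`"reverse"`)
#'   per copy; default all forward. Reverse requires a nucleotide
#'   background.
#' @param positions `"auto"` (uniformly spaced, non-overlapping) or integer
#'   vector of 1-based start positions.
#' @param indel_rate Per-position indel probability (default 0).
#' @param seed Integer seed.
#' @return A list with `sequence` (the modified [seq_record()]) and `truth`
#'   (data frame `start1, end1, start2, end2, orientation, copy_i, copy_j,
#'   realized_identity`, one row per copy pair, `start1 < start2`).
#' @export
plant_repeats <- function(background, unit_length, n_copies = 2L,
                          divergence = 0, orientation_of_copies = NULL,
                          positions = "auto", indel_rate = 0, seed = 1L) {
  background <- as_seq_record(background)
  n_copies <- as.integer(n_copies)
  stopifnot(n_copies >= 2L, unit_length >= 1L,
            divergence >= 0, divergence < 1, indel_rate >= 0, indel_rate < 1)
  if (is.null(orientation_of_copies))
    orientation_of_copies <- rep("forward", n_copies)
  stopifnot(length(orientation_of_copies) == n_copies,
            all(orientation_of_copies %in% c("forward", "reverse")))
  if (any(orientation_of_copies == "reverse") &&
      background$alphabet != "nucleotide")
    stop("reverse-oriented copies require a nucleotide background")
  pool <- if (background$alphabet == "nucleotide") NUC_CORE else PROT_CORE

  with_seed(seed, {
    template <- sample(pool, unit_length, replace = TRUE)
    units <- vector("list", n_copies)
    units[[1L]] <- template
    for (k in seq_len(n_copies)[-1L]) {
      u <- mutate_subs(template, divergence, pool)
      if (indel_rate > 0) u <- mutate_indels(u, indel_rate, pool)
      units[[k]] <- u
    }
    lens <- vapply(units, length, integer(1))
    L <- background$length
    if (identical(positions, "auto")) {
      gap <- (L - sum(lens)) %/% (n_copies + 1L)
      if (gap < 0L)
        stop("background too short to host ", n_copies, " copies of length ~",
             unit_length)
      positions <- integer(n_copies)
      pos <- 1L
      for (k in seq_len(n_copies)) {
        pos <- pos + gap
        positions[k] <- pos
        pos <- pos + lens[k]
      }
    } else {
      positions <- as.integer(positions)
      stopifnot(length(positions) == n_copies)
    }
    ends <- positions + lens - 1L
    if (any(positions < 1L) || any(ends > L))
      stop("planted copies do not fit inside the background")
    ord <- order(positions)
    if (any(positions[ord][-1L] <= ends[ord][-n_copies]))
      stop("planted copies overlap")

    res <- background$residues
    for (k in seq_len(n_copies)) {
      written <- paste(units[[k]], collapse = "")
      if (orientation_of_copies[k] == "reverse") written <- revcomp(written)
      substr(res, positions[k], ends[k]) <- written
    }
    out_seq <- seq_record(background$id, res, background$alphabet)

    pairs <- utils::combn(n_copies, 2L)
    truth <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(c) {
      i <- pairs[1L, c]; j <- pairs[2L, c]
      ori <- if (orientation_of_copies[i] == orientation_of_copies[j])
        "forward" else "reverse"
      ui <- units[[i]]; uj <- units[[j]]
      realized <- if (length(ui) == length(uj) && indel_rate == 0) {
        mean(ui == uj)
      } else {
        pa <- Biostrings::pairwiseAlignment(
          paste(ui, collapse = ""), paste(uj, collapse = ""),
          type = "global")
        Biostrings::pid(pa) / 100
      }
      a <- if (positions[i] <= positions[j]) i else j
      b <- if (positions[i] <= positions[j]) j else i
      data.frame(start1 = positions[a], end1 = ends[a],
                 start2 = positions[b], end2 = ends[b],
                 orientation = ori, copy_i = a, copy_j = b,
                 realized_identity = realized, stringsAsFactors = FALSE)
    }))
    rownames(truth) <- NULL
    list(sequence = out_seq, truth = truth)
  })
}
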