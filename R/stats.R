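check_intervals <- function(seq_length, pairs) {
  if (nrow(pairs) == 0L) return(invisible(TRUE))
  ok <- pairs$start1 >= 1L & pairs$end1 <= seq_length &
        pairs$start2 >= 1L & pairs$end2 <= seq_length &
        pairs$start1 <= pairs$end1 & pairs$start2 <= pairs$end2
  if (!all(ok))
    stop("repeat-pair interval out of range [1, ", seq_length, "]")
  invisible(TRUE)
}

#' Per-position repeat depth profile
#'
#' Counts, for every residue position, how many repeat-pair interval
#' occurrences cover it; both intervals of a self-pair count separately.
#' Gap columns inside alignments create no coverage outside the stated
#' intervals.
#'
#' @param seq_length Sequence length.
#' @param pairs A `repeat_pairs` data frame.
#' @param seq_id Identifier stored in the profile (defaults to the pairs'
#'   first id, or `"seq"` when empty).
#' @return An object of class `depth_profile`: list with `seq_id` and
#'   integer vector `depth` of length `seq_length`.
#' @export
repeat_depth <- function(seq_length, pairs, seq_id = NULL) {
  seq_length <- as.integer(seq_length)
  stopifnot(seq_length >= 1L)
  check_intervals(seq_length, pairs)
  if (is.null(seq_id))
    seq_id <- if (nrow(pairs)) pairs$seq_id_1[1L] else "seq"
  delta <- integer(seq_length + 1L)
  for (k in seq_len(nrow(pairs))) {
    delta[pairs$start1[k]] <- delta[pairs$start1[k]] + 1L
    delta[pairs$end1[k] + 1L] <- delta[pairs$end1[k] + 1L] - 1L
    delta[pairs$start2[k]] <- delta[pairs$start2[k]] + 1L
    delta[pairs$end2[k] + 1L] <- delta[pairs$end2[k] + 1L] - 1L
  }
  structure(list(seq_id = seq_id, depth = cumsum(delta)[seq_len(seq_length)]),
            class = "depth_profile")
}

#' Intragenic repeat density index rho
#'
#' rho is the fraction of positions covered by at least one repeat-pair
#' interval: `covered_positions / seq_length`, bounded in `[0, 1]` and
#' comparable across sequences of different length. With `region = c(lo,
#' hi)` the pair intervals are clipped to that sub-interval first and the
#' denominator is the region length (pairs falling entirely outside
#' contribute nothing).
#'
#' @inheritParams repeat_depth
#' @param region Optional `c(start, end)` sub-interval (1-based inclusive).
#' @return An object of class `density_result`: list with `seq_id`, `rho`,
#'   `covered_positions`, `seq_length`.
#' @export
repeat_density <- function(seq_length, pairs, seq_id = NULL, region = NULL) {
  prof <- repeat_depth(seq_length, pairs, seq_id)
  depth <- prof$depth
  if (!is.null(region)) {
    stopifnot(length(region) == 2L, region[1L] >= 1L,
              region[2L] <= seq_length, region[1L] <= region[2L])
    depth <- depth[region[1L]:region[2L]]
  }
  structure(list(seq_id = prof$seq_id,
                 rho = sum(depth >= 1L) / length(depth),
                 covered_positions = sum(depth >= 1L),
                 seq_length = length(depth)),
            class = "density_result")
}

#' @export
print.density_result <- function(x, ...) {
  cat(sprintf("density_result '%s': rho = %.4f (%d of %d positions)\n",
              x$seq_id, x$rho, x$covered_positions, x$seq_length))
  invisible(x)
}

#' Histogram of repeat-pair identities in 0.05 bins
#'
#' 20 half-open bins `[a, a + 0.05)` over `[0, 1]`, the last bin closed at
#' 1.0 so that perfect repeats land in `[0.95, 1.00]`.
#'
#' @param pairs A `repeat_pairs` data frame, or a numeric vector of
#'   identities in `[0, 1]`.
#' @return An object of class `identity_histogram`: list with `bin_edges`
#'   (21 values), `counts` (20), `modal_bin` and `rarest_bin` (indices of
#'   the most and least populated non-empty bins; `NA` when empty), and
#'   `n_pairs`.
#' @export
identity_histogram <- function(pairs) {
  ident <- if (is.numeric(pairs)) pairs else pairs$identity
  stopifnot(all(ident >= 0 & ident <= 1))
  edges <- 0:20 / 20
  # epsilon absorbs float error in identity * 20 at bin boundaries
  idx <- pmin(20L, as.integer(floor(ident * 20 + 1e-9)) + 1L)
  counts <- tabulate(idx, nbins = 20L)
  nonempty <- which(counts > 0L)
  structure(list(
    bin_edges = edges, counts = counts,
    modal_bin = if (length(nonempty)) nonempty[which.max(counts[nonempty])]
                else NA_integer_,
    rarest_bin = if (length(nonempty)) nonempty[which.min(counts[nonempty])]
                 else NA_integer_,
    n_pairs = length(ident)),
    class = "identity_histogram")
}

#' Bin label helper for identity histograms
#'
#' @param bin Bin index (1..20) as returned in `modal_bin` / `rarest_bin`.
#' @return A label like `"[0.65,0.70)"` (the last bin prints as
#'   `"[0.95,1.00]"`), or `NA` for an `NA` bin.
#' @export
identity_bin_label <- function(bin) {
  ifelse(is.na(bin), NA_character_,
         sprintf("[%.2f,%.2f%s", (bin - 1) / 20, bin / 20,
                 ifelse(bin == 20L, "]", ")")))
}

#' Detect containment of one sequence within another
#'
#' The fusion-gene / annotation-artifact signature: the query aligning over
#' (nearly) its full length inside the subject at high identity. Coverage is
#' the fraction of query positions under the union of the pairs' query
#' intervals; `best_identity` is the identity of the pair covering the most
#' query positions (ties broken toward higher identity).
#'
#' @param pairs Cross-comparison pairs from [find_cross_repeats()] with the
#'   query as sequence A.
#' @param len_query,len_subject Sequence lengths.
#' @param coverage_threshold Minimum query coverage. Default 0.95.
#' @param identity_threshold Minimum best identity. Default 1.0.
#' @return An object of class `containment_report`: list with `query_id`,
#'   `subject_id`, `coverage_of_query`, `best_identity`, `contained`.
#' @export
detect_containment <- function(pairs, len_query, len_subject,
                               coverage_threshold = 0.95,
                               identity_threshold = 1.0) {
  len_query <- as.integer(len_query)
  if (nrow(pairs) == 0L) {
    return(structure(list(query_id = NA_character_,
                          subject_id = NA_character_,
                          coverage_of_query = 0, best_identity = 0,
                          contained = FALSE),
                     class = "containment_report"))
  }
  covered <- logical(len_query)
  for (k in seq_len(nrow(pairs)))
    covered[pairs$start1[k]:pairs$end1[k]] <- TRUE
  coverage <- sum(covered) / len_query
  ord <- order(-pairs$length1, -pairs$identity)
  best_identity <- pairs$identity[ord[1L]]
  structure(list(
    query_id = pairs$seq_id_1[1L], subject_id = pairs$seq_id_2[1L],
    coverage_of_query = coverage, best_identity = best_identity,
    contained = coverage >= coverage_threshold &&
                best_identity >= identity_threshold),
    class = "containment_report")
}

#' Compare repeat density between two groups of sequences
#'
#' Welch two-sample t-test (two-sided) on the rho values of the two groups.
#' When both groups have zero variance the t-test is degenerate: p is 1 when
#' the means are equal and 0 otherwise, with a warning.
#'
#' @param group_a,group_b Lists of `density_result` objects, or numeric
#'   vectors of rho values; each of size >= 2.
#' @return A list with `t_statistic`, `p_value`, `mean_a`, `mean_b`.
#' @export
compare_density <- function(group_a, group_b) {
  rho_of <- function(g) {
    if (is.numeric(g)) return(g)
    vapply(g, function(x) x$rho, numeric(1))
  }
  a <- rho_of(group_a); b <- rho_of(group_b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    warning("zero variance in both groups; degenerate t-test")
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(t_statistic = if (eq) 0 else sign(mean(a) - mean(b)) * Inf,
                p_value = if (eq) 1 else 0,
                mean_a = mean(a), mean_b = mean(b)))
  }
  tt <- t.test(a, b, var.equal = FALSE)
  list(t_statistic = unname(tt$statistic), p_value = tt$p.value,
       mean_a = mean(a), mean_b = mean(b))
}
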