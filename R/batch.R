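#' Read a flat key=value configuration file
#'
#' One `key = value` pair per line; blank lines and lines starting with `#`
#' are ignored. Values are parsed as numbers when possible, `true`/`false`
#' as logicals. Recognized keys are the [align_params()] field names.
#'
#' @param path Path to the config file.
#' @return A named list of values.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("bad config line: ", ln)
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <-
      if (!is.na(num)) num
      else if (tolower(val) %in% c("true", "false")) tolower(val) == "true"
      else val
  }
  out
}

## merge config values into align_params; unknown keys are an error
params_with_config <- function(params, config) {
  known <- names(align_params())
  for (key in names(config)) {
    if (!key %in% known) stop("unknown config key: ", key)
    params[[key]] <- config[[key]]
  }
  do.call(align_params, params[known])
}

sanitize_id <- function(id) gsub("[^A-Za-z0-9._-]", "_", id)

#' Batch self-comparison over a multi-FASTA file
#'
#' Each record is processed independently with [find_self_repeats()]; per
#' record a repeat table (`<id>.repeats.tsv`), dot-plot coordinates
#' (`<id>.dots.tsv`) and a depth profile (`<id>.depth.tsv`) are written to
#' `out_dir`, plus one `summary.tsv` with a row per record: `seq_id,
#' length, n_pairs, n_perfect, n_degenerate, rho, modal_identity_bin`.
#' Records shorter than `2 * min_length` yield zero pairs with a warning;
#' per-record failures are warned about and skipped. Filename collisions
#' after id sanitization get a numeric suffix.
#'
#' @param input Path to a (multi-)FASTA file.
#' @param out_dir Output directory (created if missing).
#' @param params An [align_params()] object.
#' @param alphabet Alphabet passed to [read_fasta()].
#' @param config Optional path to a key=value config file; explicit
#'   `params` fields win over config values only when `params` is omitted
#'   (precedence: caller > config > defaults).
#' @return The summary data frame, invisibly.
#' @export
run_batch <- function(input, out_dir, params = align_params(),
                      alphabet = "auto", config = NULL) {
  if (!is.null(config))
    params <- params_with_config(unclass(params), read_config(config))
  records <- read_fasta(input, alphabet)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  used <- character(0)
  rows <- list()
  for (rec in records) {
    base <- sanitize_id(rec$id)
    if (base %in% used) {
      k <- 2L
      while (sprintf("%s.%d", base, k) %in% used) k <- k + 1L
      warning("sanitized id collision for '", rec$id, "'; using suffix .", k)
      base <- sprintf("%s.%d", base, k)
    }
    used <- c(used, base)
    pairs <- tryCatch(find_self_repeats(rec, params),
                      error = function(e) {
                        warning("record '", rec$id, "' failed: ",
                                conditionMessage(e))
                        NULL
                      })
    if (is.null(pairs)) next
    write_repeats_tsv(pairs, file.path(out_dir, paste0(base, ".repeats.tsv")))
    write_dot_coordinates(pairs, file.path(out_dir, paste0(base, ".dots.tsv")))
    prof <- repeat_depth(rec$length, pairs, seq_id = rec$id)
    write.table(
      data.frame(position = seq_len(rec$length), depth = prof$depth),
      file.path(out_dir, paste0(base, ".depth.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    dens <- repeat_density(rec$length, pairs, seq_id = rec$id)
    hist <- identity_histogram(pairs)
    perfect <- sum(pairs$identity == 1)
    rows[[length(rows) + 1L]] <- data.frame(
      seq_id = rec$id, length = rec$length, n_pairs = nrow(pairs),
      n_perfect = perfect, n_degenerate = nrow(pairs) - perfect,
      rho = dens$rho,
      modal_identity_bin = if (is.na(hist$modal_bin)) NA_character_
                           else identity_bin_label(hist$modal_bin),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no records were processed successfully")
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  out <- summary
  out$rho <- sprintf("%.4f", out$rho)
  write.table(out, file.path(out_dir, "summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(summary)
}
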