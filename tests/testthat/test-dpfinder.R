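test_that("a planted perfect duplication is reported at its exact location", {
  pairs <- find_self_repeats(
    seq_record("g", "AAGGCTTTTTAAGGCT"),
    align_params(min_length = 4, min_score = 4, min_identity = 0.9))
  fwd <- pairs[pairs$orientation == "forward", ]
  expect_equal(nrow(fwd), 1L)
  expect_equal(unlist(fwd[, c("start1", "end1", "start2", "end2")],
                      use.names = FALSE), c(1L, 6L, 11L, 16L))
  expect_equal(fwd$identity, 1)
})

test_that("an inverted repeat is reported as a canonical reverse pair", {
  pairs <- find_self_repeats(
    seq_record("g", "AAGGCCTT"), align_params(min_length = 4, min_score = 4))
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$orientation, "reverse")
  expect_equal(unlist(pairs[, c("start1", "end1", "start2", "end2")],
                      use.names = FALSE), c(1L, 4L, 5L, 8L))
  expect_equal(pairs$identity, 1)
  # the second interval aligns after reverse complementation
  expect_equal(gsub("-", "", pairs$aligned_seq2),
               revcomp(substr("AAGGCCTT", pairs$start2, pairs$end2)))
})

test_that("degenerate planted repeats are recovered with faithful identity", {
  for (seed in 1:5) {
    pl <- plant_one_dup(seed, L = 500L, unit = 100L, divergence = 0.2)
    truth <- pl$truth
    pairs <- find_self_repeats(pl$sequence)
    expect_gte(nrow(pairs), 1L)
    best <- pairs[which.max(pairs$score), ]
    # identity close to the realized (not just nominal) divergence
    expect_lt(abs(best$identity - truth$realized_identity), 0.05)
    expect_lt(abs(best$identity - 0.8), 0.1)
    expect_gte(jaccard(c(best$start1, best$end1),
                       c(truth$start1, truth$end1)), 0.9)
    expect_gte(jaccard(c(best$start2, best$end2),
                       c(truth$start2, truth$end2)), 0.9)
  }
})

test_that("the trivial self-diagonal is never reported", {
  s <- random_sequence(300, seed = 21)
  pairs <- find_self_repeats(s)
  if (nrow(pairs)) {
    expect_true(all(pairs$start1 < pairs$start2))
    expect_false(any(pairs$start1 == pairs$start2 &
                     pairs$end1 == pairs$end2))
  }
  expect_true(all(pairs$identity >= 0.45 & pairs$identity <= 1))
})

test_that("short sequences warn and return an empty table", {
  expect_warning(p <- find_self_repeats(seq_record("tiny", "ACGTACGT")),
                 "shorter than 2\\*min_length")
  expect_equal(nrow(p), 0L)
})

test_that("sequences beyond the quadratic-DP limit are rejected", {
  long <- seq_record("big", strrep("A", 50001L))
  expect_error(find_self_repeats(long), "sliding_window_dotmatrix")
})

test_that("a tandem array yields a perfect-identity covering set of pairs", {
  unit <- random_sequence(50, seed = 3)$residues
  s <- seq_record("t", paste0(random_sequence(100, seed = 4)$residues,
                              strrep(unit, 4),
                              random_sequence(100, seed = 5)$residues))
  pairs <- find_self_repeats(s, align_params(min_length = 30))
  fwd <- pairs[pairs$orientation == "forward", ]
  expect_gte(nrow(fwd), 3L)
  expect_true(all(fwd$identity == 1))
  # every copy-pair offset (50, 100, 150) appears as a reported diagonal
  expect_setequal(unique(fwd$start2 - fwd$start1), c(50L, 100L, 150L))
  # reported intervals jointly cover the whole array
  prof <- repeat_depth(s$length, fwd)
  expect_true(all(prof$depth[101:300] >= 1L))
})

test_that("reverse-complementing the input maps the pair set coordinates", {
  pl1 <- plant_one_dup(31, L = 800L, unit = 120L, divergence = 0.1)
  pl <- plant_repeats(pl1$sequence, unit_length = 60L, n_copies = 2L,
                      orientation_of_copies = c("forward", "reverse"),
                      positions = c(330L, 450L), seed = 77L)
  s <- pl$sequence
  L <- s$length
  fwd_pairs <- find_self_repeats(s)
  rc_pairs <- find_self_repeats(seq_record(s$id, revcomp(s$residues)))
  expect_gt(nrow(fwd_pairs), 1L)
  key <- function(p) {
    df <- data.frame(s1 = p$start1, e1 = p$end1, s2 = p$start2, e2 = p$end2,
                     o = p$orientation)
    df[order(df$s1, df$s2, df$o), ]
  }
  mapped <- data.frame(s1 = L - rc_pairs$end2 + 1L,
                       e1 = L - rc_pairs$start2 + 1L,
                       s2 = L - rc_pairs$end1 + 1L,
                       e2 = L - rc_pairs$start1 + 1L,
                       o = rc_pairs$orientation)
  mapped <- mapped[order(mapped$s1, mapped$s2, mapped$o), ]
  expect_equal(key(fwd_pairs), mapped, ignore_attr = TRUE)
})

test_that("self-comparison is deterministic", {
  pl <- plant_three_dups(8)
  expect_identical(find_self_repeats(pl$sequence),
                   find_self_repeats(pl$sequence))
})

test_that("cross comparison finds containment and is symmetric", {
  inner <- random_sequence(100, seed = 41, alphabet = "protein", id = "short")
  host <- seq_record("long", paste0(
    random_sequence(300, seed = 42, alphabet = "protein")$residues,
    inner$residues,
    random_sequence(200, seed = 43, alphabet = "protein")$residues))
  ab <- find_cross_repeats(inner, host)
  expect_gte(nrow(ab), 1L)
  best <- ab[which.max(ab$score), ]
  expect_equal(best$identity, 1)
  expect_equal(c(best$start1, best$end1), c(1L, 100L))
  expect_equal(c(best$start2, best$end2), c(301L, 400L))

  ba <- find_cross_repeats(host, inner)
  expect_equal(nrow(ab), nrow(ba))
  expect_equal(ab[, c("start1", "end1")], ba[, c("start2", "end2")],
               ignore_attr = TRUE)
  expect_equal(ab[, c("start2", "end2")], ba[, c("start1", "end1")],
               ignore_attr = TRUE)
  expect_equal(ab$identity, ba$identity)
})

test_that("unrelated random proteins produce no pairs", {
  a <- random_sequence(200, seed = 51, alphabet = "protein")
  b <- random_sequence(200, seed = 52, alphabet = "protein")
  expect_equal(nrow(find_cross_repeats(a, b)), 0L)
})

test_that("extract_all dispatches to self and cross modes", {
  pl <- plant_one_dup(61, L = 400L, unit = 80L)
  expect_identical(extract_all(pl$sequence),
                   find_self_repeats(pl$sequence))
  other <- random_sequence(400, seed = 62)
  expect_identical(extract_all(pl$sequence, other),
                   find_cross_repeats(pl$sequence, other))
})

test_that("perfect pairs are contained in maximal exact repeats", {
  pl <- plant_three_dups(5)
  pairs <- find_self_repeats(pl$sequence)
  perfect <- pairs[pairs$identity == 1, ]
  expect_gte(nrow(perfect), 1L)
  exact <- find_maximal_exact_repeats(pl$sequence, min_length = 30L)
  for (k in seq_len(nrow(perfect)))
    expect_true(pair_in_exact(perfect[k, ], exact))
})

test_that("filter_lir keeps only long pairs", {
  pl <- plant_three_dups(6)
  pairs <- find_self_repeats(pl$sequence)
  lir <- filter_lir(pairs, 100L)
  expect_true(all(lir$aln_columns >= 100L))
  expect_equal(nrow(filter_lir(pairs, 1L)), nrow(pairs))
})
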