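test_that("a planted exact copy is reported maximally, not as sub-repeats", {
  s <- seq_record("p", "AAGGCTWYFPAAGGCT", alphabet = "protein")
  reps <- find_maximal_exact_repeats(s, min_length = 4)
  expect_equal(nrow(reps), 1L)
  expect_equal(unlist(reps[, c("start1", "start2", "length")],
                      use.names = FALSE), c(1L, 11L, 6L))
  expect_equal(reps$orientation, "forward")
})

test_that("palindromes split at their center into disjoint reverse copies", {
  reps <- find_maximal_exact_repeats("AAGGCCTT", min_length = 4)
  expect_equal(nrow(reps), 1L)
  expect_equal(unlist(reps[, c("start1", "start2", "length")],
                      use.names = FALSE), c(1L, 5L, 4L))
  expect_equal(reps$orientation, "reverse")
  # halves verify the reverse-complement invariant
  expect_equal(substr("AAGGCCTT", 1, 4), revcomp(substr("AAGGCCTT", 5, 8)))
})

test_that("overlapping copies in homopolymer runs follow the overlap policy", {
  reps <- find_maximal_exact_repeats("AAAA", min_length = 2,
                                     search_reverse = TRUE)
  expect_equal(reps$start1, c(1L, 1L))
  expect_equal(reps$start2, c(2L, 3L))
  expect_equal(reps$length, c(3L, 2L))
  expect_equal(reps$orientation, c("forward", "forward"))
  expect_identical(reps, brute_force_exact_repeats("AAAA", min_length = 2))
})

test_that("min_length above the sequence length yields nothing", {
  expect_equal(nrow(find_maximal_exact_repeats("ACGTACGT", 20)), 0L)
})

test_that("N never matches, even against N", {
  # without the N column the flanking runs are too short
  reps <- find_maximal_exact_repeats("ACGTNACGTN", min_length = 5,
                                     search_reverse = FALSE)
  expect_equal(nrow(reps), 0L)
  reps4 <- find_maximal_exact_repeats("ACGTNACGTN", min_length = 4,
                                      search_reverse = FALSE)
  expect_equal(unlist(reps4[, c("start1", "start2", "length")],
                      use.names = FALSE), c(1L, 6L, 4L))
})

test_that("finder matches the brute-force oracle on random sequences", {
  for (seed in 1:10) {
    L <- 50L + (seed * 53L) %% 251L
    s <- random_sequence(L, seed = seed)
    for (rev_on in c(TRUE, FALSE)) {
      expect_identical(find_maximal_exact_repeats(s, 6, rev_on),
                       brute_force_exact_repeats(s, 6, rev_on),
                       info = paste("seed", seed, "rev", rev_on))
    }
  }
  # ambiguity-rich sequences: ~10% N
  for (seed in 1:5) {
    base <- strsplit(random_sequence(150, seed = seed)$residues, "")[[1]]
    idx <- seq(5, 150, by = 10)
    base[idx] <- "N"
    s <- seq_record("n", paste(base, collapse = ""))
    expect_identical(find_maximal_exact_repeats(s, 5, TRUE),
                     brute_force_exact_repeats(s, 5, TRUE),
                     info = paste("N seed", seed))
  }
})

test_that("repeat sets shrink monotonically with min_length", {
  s <- random_sequence(400, seed = 77)
  r5 <- find_maximal_exact_repeats(s, 5, TRUE)
  r6 <- find_maximal_exact_repeats(s, 6, TRUE)
  key <- function(r) paste(r$start1, r$start2, r$length, r$orientation)
  expect_true(all(key(r6) %in% key(r5)))
  expect_lte(nrow(r6), nrow(r5))
})

test_that("every reported repeat verifies its substring invariant", {
  pl <- plant_repeats(random_sequence(600, seed = 88), unit_length = 70L,
                      n_copies = 2L,
                      orientation_of_copies = c("forward", "reverse"),
                      seed = 89L)
  s <- pl$sequence
  reps <- find_maximal_exact_repeats(s, 10, TRUE)
  expect_gte(nrow(reps), 1L)
  expect_true("reverse" %in% reps$orientation)
  for (k in seq_len(nrow(reps))) {
    c1 <- substr(s$residues, reps$start1[k], reps$start1[k] + reps$length[k] - 1L)
    c2 <- substr(s$residues, reps$start2[k], reps$start2[k] + reps$length[k] - 1L)
    if (reps$orientation[k] == "forward") expect_equal(c1, c2)
    else expect_equal(c1, revcomp(c2))
  }
})
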