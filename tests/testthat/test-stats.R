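test_that("depth counts both intervals of every pair", {
  expect_equal(repeat_depth(5, make_pair(1, 1, 1, 1)[0, ])$depth, rep(0L, 5))
  expect_equal(repeat_depth(8, make_pair(1, 4, 5, 8))$depth, rep(1L, 8))
  expect_equal(repeat_depth(6, make_pair(1, 4, 3, 6))$depth,
               c(1L, 1L, 2L, 2L, 1L, 1L))
  expect_error(repeat_depth(6, make_pair(1, 4, 5, 8)), "out of range")
})

test_that("depth conserves total interval length and is monotone", {
  pl <- plant_three_dups(11)
  pairs <- find_self_repeats(pl$sequence)
  prof <- repeat_depth(pl$sequence$length, pairs)
  expect_equal(sum(prof$depth), sum(pairs$length1) + sum(pairs$length2))
  # adding a pair never decreases depth anywhere
  sub <- pairs[-1, ]
  d_sub <- repeat_depth(pl$sequence$length, sub)$depth
  expect_true(all(prof$depth >= d_sub))
  expect_gte(repeat_density(pl$sequence$length, pairs)$rho,
             repeat_density(pl$sequence$length, sub)$rho)
})

test_that("rho is the covered fraction", {
  expect_equal(repeat_density(10, make_pair(1, 4, 5, 8)[0, ])$rho, 0)
  expect_equal(repeat_density(8, make_pair(1, 4, 5, 8))$rho, 1)
  d <- repeat_density(10, make_pair(1, 4, 5, 8))
  expect_equal(d$rho, 0.8)
  expect_equal(d$covered_positions, 8L)
})

test_that("region-restricted rho clips intervals to the region", {
  pairs <- make_pair(1, 4, 5, 8)
  expect_equal(repeat_density(20, pairs, region = c(1, 10))$rho, 0.8)
  expect_equal(repeat_density(20, pairs, region = c(3, 6))$rho, 1)
  expect_equal(repeat_density(20, pairs, region = c(11, 20))$rho, 0)
})

test_that("identity histogram follows the 0.05 binning and edge rules", {
  h <- identity_histogram(c(0.67, 0.68, 0.92))
  expect_equal(h$counts[14], 2L)   # [0.65, 0.70)
  expect_equal(h$counts[19], 1L)   # [0.90, 0.95)
  expect_equal(sum(h$counts), 3L)
  expect_equal(h$modal_bin, 14L)
  expect_equal(identity_bin_label(h$modal_bin), "[0.65,0.70)")

  edge <- identity_histogram(c(0.65, 0.70, 1.0, 0.95))
  expect_equal(edge$counts[14], 1L)  # 0.65 opens its own bin
  expect_equal(edge$counts[15], 1L)  # 0.70 belongs to [0.70, 0.75)
  expect_equal(edge$counts[20], 2L)  # 1.0 in the closed last bin
  # identities arising as ratios land on the correct side of edges
  frac <- identity_histogram(c(13 / 20, 14 / 20, 7 / 10))
  expect_equal(frac$counts[14], 1L)
  expect_equal(frac$counts[15], 2L)

  empty <- identity_histogram(numeric(0))
  expect_equal(sum(empty$counts), 0L)
  expect_true(is.na(empty$modal_bin))
})

test_that("histogram counts conserve the number of pairs", {
  pl <- plant_three_dups(12)
  pairs <- find_self_repeats(pl$sequence)
  h <- identity_histogram(pairs)
  expect_equal(sum(h$counts), nrow(pairs))
  expect_true(all(pairs$identity >= 0.45 & pairs$identity <= 1))
})

test_that("containment reports coverage and identity of the query", {
  pairs <- make_pair(1, 100, 301, 400, id = "q")
  pairs$seq_id_2 <- "s"
  rep_full <- detect_containment(pairs, 100, 1000)
  expect_true(rep_full$contained)
  expect_equal(rep_full$coverage_of_query, 1)
  expect_equal(rep_full$best_identity, 1)

  none <- detect_containment(pairs[0, ], 100, 1000)
  expect_false(none$contained)
  expect_equal(none$coverage_of_query, 0)

  half <- detect_containment(make_pair(1, 50, 301, 350, id = "q"), 100, 1000)
  expect_false(half$contained)
  expect_equal(half$coverage_of_query, 0.5)
})

test_that("density comparison is a Welch t-test with guarded degeneracy", {
  g <- c(0.2, 0.4, 0.6)
  same <- compare_density(g, g)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)

  expect_warning(deg <- compare_density(c(0, 0, 0), c(1, 1, 1)),
                 "zero variance")
  expect_equal(deg$p_value, 0)
  expect_error(compare_density(0.5, c(0.1, 0.2)), "at least 2")

  set.seed(13)
  a <- runif(8); b <- runif(10)
  res <- compare_density(a, b)
  orc <- oracle_welch(a, b)
  expect_equal(res$t_statistic, orc$t)
  expect_equal(res$p_value, orc$p)
  # antisymmetry of t, invariance of p
  flip <- compare_density(b, a)
  expect_equal(flip$t_statistic, -res$t_statistic)
  expect_equal(flip$p_value, res$p_value)
})

test_that("groups separated by 0.3 in mean rho give p below 0.001", {
  set.seed(17)
  a <- pmin(1, pmax(0, rnorm(20, 0.5, 0.1)))
  b <- pmin(1, pmax(0, rnorm(20, 0.2, 0.1)))
  res <- compare_density(a, b)
  expect_lt(res$p_value, 0.001)
  expect_gt(res$mean_a, res$mean_b)
})
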