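test_that("p-value estimator counts extreme permutations with the identity correction", {
  expect_equal(spice_p_value(0.9, runif(999, -0.5, 0.5)), 0.001)
  expect_equal(spice_p_value(0.5, c(0.6, 0.2, -0.7, 0.1)), 0.6) # (1 + 2) / 5
  # exact ties count toward the numerator
  expect_equal(spice_p_value(0.5, c(0.5, 0.1)), 2 / 3)
  expect_equal(spice_p_value(-0.5, c(0.5, 0.1)), 2 / 3) # magnitudes compared
  # one-sided variant compares signed values
  expect_equal(spice_p_value(-0.5, c(0.5, 0.1), sidedness = "greater"), 1)
  expect_equal(spice_p_value(0.9, c(0.5, 0.1), sidedness = "greater"), 1 / 3)
})

test_that("with two subjects the null statistics take only the two attainable values", {
  d <- toy_coupled_dataset(n = 2, v = 25, seed = 5)
  a_id <- oracle_a_stat(d$x, d$y, c(1, 2))
  a_swap <- oracle_a_stat(d$x, d$y, c(2, 1))
  ak <- permute_and_score(d, k = 200, seed = 11)
  expect_true(all(
    abs(ak - a_id) < 1e-12 | abs(ak - a_swap) < 1e-12
  ))
  expect_gt(sum(abs(ak - a_swap) < 1e-12), 0) # both orders get sampled
})

test_that("the same seed reproduces the identical permutation stream", {
  d <- toy_null_dataset(n = 7, v = 30, seed = 1)
  r1 <- spice_test(d, k = 50, seed = 123)
  r2 <- spice_test(d, k = 50, seed = 123)
  expect_identical(r1$null_stats, r2$null_stats)
  expect_identical(r1$p_value, r2$p_value)
  # the standalone scorer shares the stream with spice_test
  expect_identical(permute_and_score(d, k = 50, seed = 123), r1$null_stats)
  # a drawn seed is recorded and reproduces the run
  r3 <- spice_test(d, k = 20)
  expect_identical(spice_test(d, k = 20, seed = r3$seed)$p_value, r3$p_value)
})

test_that("sampled permutations match the exhaustive distribution (n = 3)", {
  d <- toy_null_dataset(n = 3, v = 15, seed = 4)
  perms <- all_perms(1:3)
  a_all <- apply(perms, 1, function(p) oracle_a_stat(d$x, d$y, p))
  expect_equal(length(unique(round(a_all, 12))), 6)

  k <- 10000
  ak <- permute_and_score(d, k = k, seed = 21)
  # each of the 6 permutations should appear with frequency 1/6
  for (a in a_all) {
    freq <- mean(abs(ak - a) < 1e-12)
    expect_lt(abs(freq - 1 / 6), 3 * sqrt((1 / 6) * (5 / 6) / k))
  }
  expect_equal(sum(vapply(a_all, function(a) sum(abs(ak - a) < 1e-12), 0)), k)
})

test_that("Monte-Carlo p-values converge to the exhaustive-enumeration oracle", {
  for (seed in c(2, 8)) {
    d <- toy_coupled_dataset(n = 4, v = 12, noise = 2.5, seed = seed)
    p_exact <- oracle_exact_p(d$x, d$y)
    k <- 4000
    res <- spice_test(d, k = k, seed = seed + 100)
    expect_lt(abs(res$p_value - p_exact),
              3 * sqrt(p_exact * (1 - p_exact) / k) + 2 / (k + 1))
  }
})

test_that("result object satisfies its structural invariants", {
  d <- toy_coupled_dataset(n = 6, v = 20, seed = 3)
  res <- spice_test(d, k = 99, seed = 7)
  expect_s3_class(res, "spice_result")
  expect_length(res$null_stats, res$k_permutations)
  expect_true(all(abs(c(res$a0, res$null_stats)) <= 1))
  expect_gte(res$p_value, 1 / (res$k_permutations + 1))
  expect_lte(res$p_value, 1)
  expect_identical(res$p_value,
                   spice_p_value(res$a0, res$null_stats, res$sidedness))
  expect_equal(res$a0, oracle_a_stat(d$x, d$y))
  expect_identical(res$n_subjects, 6L)
  expect_identical(res$n_locations, 20L)
})

test_that("two-sided p is invariant to a common affine rescaling of the Y maps", {
  d <- toy_coupled_dataset(n = 8, v = 30, noise = 1, seed = 6)
  base <- spice_test(d, k = 199, seed = 31)
  for (slope in c(2.5, -1.3)) {
    d2 <- modality_dataset(d$x, slope * d$y + 4)
    res <- spice_test(d2, k = 199, seed = 31)
    expect_equal(res$p_value, base$p_value)
    expect_equal(abs(res$a0), abs(base$a0), tolerance = 1e-12)
  }
})

test_that("the Spearman variant scores permutations on ranks", {
  d <- toy_coupled_dataset(n = 5, v = 18, noise = 1, seed = 12)
  res <- spice_test(d, measure = "spearman", k = 500, seed = 9)
  expect_equal(res$a0, oracle_a_stat(d$x, d$y, method = "spearman"))
  p_exact <- oracle_exact_p(d$x, d$y, method = "spearman")
  expect_lt(abs(res$p_value - p_exact),
            3 * sqrt(max(p_exact * (1 - p_exact), 0.001) / 500) + 2 / 501)
})

test_that("masked locations are excluded from the permutation test", {
  d <- toy_coupled_dataset(n = 6, v = 40, seed = 13)
  mask <- rep(c(TRUE, FALSE), c(30, 10))
  dm <- modality_dataset(d$x, d$y, mask = mask)
  dslice <- modality_dataset(d$x[, mask], d$y[, mask])
  rm_ <- spice_test(dm, k = 99, seed = 17)
  rs <- spice_test(dslice, k = 99, seed = 17)
  expect_identical(rm_$p_value, rs$p_value)
  expect_equal(rm_$a0, rs$a0)
  expect_identical(rm_$n_locations, 30L)
})
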