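test_that("mean-map pairs hit the target correlation essentially exactly", {
  mm0 <- make_mean_maps(200, rho_target = 0, seed = 1)
  expect_lt(abs(mm0$rho_empirical), 1e-10)
  mm <- make_mean_maps(10242, rho_target = -0.15, seed = 2)
  expect_lt(abs(mm$rho_empirical + 0.15), 1e-10)
  expect_equal(stats::cor(mm$m1, mm$m2), mm$rho_empirical, tolerance = 1e-12)
  # maps are standardized
  expect_equal(mean(mm$m1), 0, tolerance = 1e-12)
  expect_equal(stats::sd(mm$m2), 1, tolerance = 1e-10)
  expect_error(make_mean_maps(100, rho_target = 1), "inside \\(-1, 1\\)")
  expect_error(make_mean_maps(100, rho_target = -1.2), "inside \\(-1, 1\\)")
})

test_that("lattice smoothing raises spatial autocorrelation of the mean maps", {
  lag1 <- function(v) stats::cor(v[-1], v[-length(v)])
  rough <- make_mean_maps(2000, -0.15, smoothness = 0, seed = 3)
  smooth <- make_mean_maps(2000, -0.15, smoothness = 5, seed = 3)
  expect_gt(lag1(smooth$m1), lag1(rough$m1))
  expect_gt(lag1(smooth$m2), lag1(rough$m2))
  expect_lt(abs(smooth$rho_empirical + 0.15), 1e-10)
})

test_that("simulated datasets follow the shared-signal model and are reproducible", {
  mm <- make_mean_maps(300, -0.15, seed = 4)
  cfg <- simulation_config(n = 12, sigma_a_sq = 3, sigma_e_sq = 0.5,
                           mean_maps = mm, seed = 99)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$x, d2$x)
  expect_identical(d1$y, d2$y)
  expect_identical(dim(d1), c(12L, 300L))

  # vanishing noise: each subject's within correlation approaches the
  # mean-map correlation (the shared a_i scales both maps identically)
  cfg0 <- simulation_config(n = 10, sigma_a_sq = 3, sigma_e_sq = 1e-12,
                            mean_maps = mm, seed = 5)
  d0 <- simulate_dataset(cfg0)
  within <- vapply(1:10, function(i) stats::cor(d0$x[i, ], d0$y[i, ]), 0)
  expect_equal(within, rep(mm$rho_empirical, 10), tolerance = 1e-4)
})

test_that("under the null every subject's signal is identical to the mean map", {
  mm <- make_mean_maps(300, -0.15, seed = 6)
  cfg <- simulation_config(n = 8, sigma_a_sq = 0, sigma_e_sq = 1e-12,
                           mean_maps = mm, seed = 7)
  d <- simulate_dataset(cfg)
  for (i in 1:8) expect_equal(d$x[i, ], mm$m1, tolerance = 1e-5)
})

test_that("a positive signal variance makes within-subject similarity dominate", {
  mm <- make_mean_maps(300, -0.15, seed = 8)
  within <- between <- numeric(0)
  for (r in 1:20) {
    cfg <- simulation_config(n = 10, sigma_a_sq = 1.5, sigma_e_sq = 0.5,
                             mean_maps = mm, seed = 100 + r)
    d <- simulate_dataset(cfg)
    cm <- abs(stats::cor(t(d$x), t(d$y)))
    within <- c(within, mean(diag(cm)))
    between <- c(between, mean(cm[row(cm) != col(cm)]))
  }
  expect_gt(mean(within), mean(between))
})

test_that("rejection rates are bit-reproducible and replicates re-runnable in isolation", {
  mm <- make_mean_maps(100, -0.15, seed = 9)
  cfg <- simulation_config(n = 10, sigma_a_sq = 0.5, sigma_e_sq = 1,
                           mean_maps = mm, n_replicates = 25,
                           k_permutations = 99, seed = 55)
  rr1 <- rejection_rate(cfg)
  rr2 <- rejection_rate(cfg)
  expect_identical(rr1$p_values, rr2$p_values)
  expect_identical(rr1$rejections, sum(rr1$p_values < cfg$alpha))
  expect_equal(rr1$se, sqrt(rr1$rate * (1 - rr1$rate) / 25))

  # replicate 7 alone, via the documented seed-spawning scheme
  rep_seed <- spawn_seed(55, 7)
  cfg_r <- cfg
  cfg_r$seed <- spawn_seed(rep_seed, 1)
  p7 <- spice_test(simulate_dataset(cfg_r), k = 99,
                   seed = spawn_seed(rep_seed, 2))$p_value
  expect_identical(p7, rr1$p_values[7])

  cfg1 <- simulation_config(n = 6, sigma_a_sq = 0, sigma_e_sq = 1,
                            mean_maps = mm, n_replicates = 1,
                            k_permutations = 19, seed = 3)
  expect_true(rejection_rate(cfg1)$rate %in% c(0, 1))
})

test_that("power grids carry the full schema and round-trip through TSV", {
  mm <- list(make_mean_maps(100, -0.15, seed = 10),
             make_mean_maps(100, -0.04, seed = 11))
  grid <- power_grid(n = c(8, 12), sigma_a_sq = c(0, 2), sigma_e_sq = 0.5,
                     mean_maps = mm, n_replicates = 10, k_permutations = 39,
                     seed = 77)
  expect_identical(nrow(grid), 8L)
  expect_named(grid, c("n", "sigma_a_sq", "sigma_e_sq", "rho", "alpha",
                       "replicates", "rejections", "rate", "se", "seed"))
  expect_true(all(grid$rate >= 0 & grid$rate <= 1))
  expect_setequal(round(grid$rho, 6), c(-0.15, -0.04))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_power_grid(grid, tsv)
  back <- utils::read.delim(tsv)
  expect_equal(back$rate, grid$rate)
  expect_equal(back$seed, grid$seed)

  # bit-reproducible from the grid settings plus the master seed
  grid2 <- power_grid(n = c(8, 12), sigma_a_sq = c(0, 2), sigma_e_sq = 0.5,
                      mean_maps = mm, n_replicates = 10, k_permutations = 39,
                      seed = 77)
  expect_identical(grid$rate, grid2$rate)
})

test_that("a grid can be driven from a plain-text configuration file", {
  cfg_path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n: [6, 10]",
    "sigma_a_sq: [0.0, 2.0]",
    "sigma_e_sq: [0.5]",
    "rho: [-0.15]",
    "v: 80",
    "replicates: 5",
    "permutations: 19",
    "alpha: 0.05",
    "seed: 12"
  ), cfg_path)
  grid <- run_power_grid_config(cfg_path)
  expect_identical(nrow(grid), 4L)
  expect_true(all(abs(grid$rho + 0.15) < 1e-9))
  expect_identical(grid$replicates, rep(5L, 4))
})

test_that("null simulations reject at close to the nominal rate", {
  mm <- make_mean_maps(200, -0.15, seed = 13)
  cfg <- simulation_config(n = 20, sigma_a_sq = 0, sigma_e_sq = 1.5,
                           mean_maps = mm, n_replicates = 400,
                           k_permutations = 99, seed = 14)
  rr <- rejection_rate(cfg)
  half_width <- stats::qnorm(0.995) * sqrt(0.05 * 0.95 / 400)
  expect_lt(abs(rr$rate - 0.05), half_width)
})
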