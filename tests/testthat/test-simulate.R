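test_that("locations are reproducible, snapped, and inside the domain", {
  cfg <- isoscape_sim_config(n_samples = 120, seed = 33)
  l1 <- sample_locations(cfg)
  l2 <- sample_locations(cfg)
  expect_identical(l1, l2)
  expect_true(all(l1 %% 1000 == 500))   # 1 km square centres
  d <- cfg$domain
  expect_true(all(l1[, 1] > d[1] & l1[, 1] < d[2]))
  expect_true(all(l1[, 2] > d[3] & l1[, 2] < d[4]))
})

test_that("a degenerate single focus collapses to one grid square", {
  cfg <- isoscape_sim_config(n_samples = 30, n_clusters = 1, cluster_sd = 0,
                             seed = 4)
  loc <- sample_locations(cfg)
  expect_equal(nrow(unique(loc)), 1L)
})

test_that("clustered sampling yields right-skewed nearest-neighbour distances", {
  cfg <- isoscape_sim_config(n_samples = 258, n_clusters = 25, seed = 6)
  loc <- sample_locations(cfg)
  D <- as.matrix(dist(loc))
  nn <- apply(D + diag(Inf, nrow(loc)), 1, min)
  expect_gt(max(nn), 3 * median(nn))
  expect_gt(mean(nn), median(nn))   # right skew
})

test_that("the noise-free limit returns the trend exactly", {
  cfg <- isoscape_sim_config(n_samples = 80, seed = 9,
                             variogram = stable_variogram(0, 0, 120000, 1.2))
  loc <- sample_locations(cfg)
  vals <- simulate_field(loc, cfg)
  expect_equal(vals, predict_trend(cfg$trend, loc), tolerance = 1e-12)
  # and downstream trend fitting recovers the coefficients to machine precision
  tr <- fit_trend(loc, vals, centre = cfg$trend$centre,
                  scale = cfg$trend$scale)
  expect_equal(unname(coef(tr)), unname(cfg$trend$coefficients),
               tolerance = 1e-9)
})

test_that("pure nugget noise has the configured variance", {
  cfg <- isoscape_sim_config(n_samples = 2000, seed = 10, n_clusters = 40,
                             trend_coeffs = c(17.8, 0, 0, 0, 0, 0),
                             variogram = stable_variogram(0.25, 0, 120000, 1.2))
  loc <- sample_locations(cfg)
  vals <- simulate_field(loc, cfg)
  expect_equal(var(vals), 0.25, tolerance = 0.05)
  expect_equal(mean(vals), 17.8, tolerance = 0.05)
})

test_that("coincident samples share the correlated field but not the nugget", {
  cfg <- isoscape_sim_config(n_samples = 40, n_clusters = 1, cluster_sd = 0,
                             seed = 12, trend_coeffs = c(17, 0, 0, 0, 0, 0),
                             variogram = stable_variogram(0, 0.5, 100000, 1.2))
  loc <- sample_locations(cfg)      # all coincident
  vals <- simulate_field(loc, cfg)
  expect_lt(max(vals) - min(vals), 1e-12)   # no nugget: identical values
  cfg2 <- cfg; cfg2$variogram <- stable_variogram(0.3, 0.5, 100000, 1.2)
  vals2 <- simulate_field(loc, cfg2)
  expect_gt(var(vals2), 0.05)               # nugget: independent draws
})

test_that("the simulated semivariogram tracks the generating stable model", {
  truth <- stable_variogram(0.2, 0.6, 150000, 1.3)
  cfg <- isoscape_sim_config(n_samples = 1000, n_clusters = 60,
                             cluster_sd = 60000, seed = 14,
                             trend_coeffs = c(17.8, 0, 0, 0, 0, 0),
                             variogram = truth)
  loc <- sample_locations(cfg)
  vals <- simulate_field(loc, cfg)
  ev <- empirical_variogram(loc, vals - mean(vals), max_lag = 400000,
                            n_bins = 10)
  gmod <- semivariance(truth, ev$dist)
  # binned Monte-Carlo agreement: within 25% of the model in occupied bins
  use <- ev$n_pairs > 200
  expect_true(all(abs(ev$gamma[use] - gmod[use]) / gmod[use] < 0.25))
})

test_that("migrant planting and the truth sidecar are bookkept exactly", {
  mig <- data.frame(index = c(3, 10, 50), offset = c(2, -2, 2))
  cfg <- isoscape_sim_config(n_samples = 60, migrants = mig, seed = 15)
  sim <- simulate_isoscape(cfg)
  expect_equal(sim$truth$migrant_index, c(3L, 10L, 50L))
  base <- simulate_isoscape(isoscape_sim_config(n_samples = 60, seed = 15))
  d <- sim$samples$d18Op - base$samples$d18Op
  expect_equal(d[mig$index], mig$offset)
  expect_equal(d[-mig$index], rep(0, 57))
})

test_that("datasets round-trip through the table reader", {
  sim <- simulate_isoscape(isoscape_sim_config(n_samples = 25, seed = 16))
  dir <- tempfile()
  paths <- write_dataset(sim, dir)
  back <- read_samples(paths[["samples"]])
  expect_equal(back$d18Op, sim$samples$d18Op)
  expect_equal(back$easting, sim$samples$easting)
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$variogram$nugget, 0.299684)
})

test_that("the study-scale preset spans a realistic per-mil range", {
  cfg <- sim_config_paper(seed = 17)
  expect_equal(cfg$n_samples, 258L)
  expect_equal(cfg$variogram$range, 121384.818021)
  loc <- sample_locations(cfg)
  trend_vals <- predict_trend(cfg$trend, loc)
  expect_true(all(trend_vals > 16 & trend_vals < 20))
  vals <- simulate_field(loc, cfg)
  expect_gt(mean(vals > 16 & vals < 20), 0.95)
})
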