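test_that("the stable model obeys its defining identities", {
  vg <- stable_variogram(0.299684, 0.015628, 121384.818021, 1.170313)
  expect_equal(semivariance(vg, 0), 0)
  # value at the practical range: c0 + c (1 - e^-3)
  expect_equal(semivariance(vg, vg$range),
               0.299684 + 0.015628 * (1 - exp(-3)))
  # monotone non-decreasing out to 10 range, sill approached from below
  h <- seq(1, 10 * vg$range, length.out = 2000)
  g <- semivariance(vg, h)
  expect_true(all(diff(g) >= -1e-12))
  expect_true(all(g <= vg$nugget + vg$psill + 1e-12))
  expect_equal(g[length(g)], vg$nugget + vg$psill, tolerance = 1e-6)
  # shape 2 equals the Gaussian model formula
  vg2 <- stable_variogram(0.1, 1, 50000, shape = 2)
  expect_equal(semivariance(vg2, 30000),
               0.1 + 1 * (1 - exp(-3 * (30000 / 50000)^2)))
  expect_error(stable_variogram(0.1, 1, 50000, shape = 2.5))
})

test_that("two samples give the definitional single-bin estimate", {
  loc <- cbind(c(0, 10000), c(0, 0))
  suppressWarnings(ev <- empirical_variogram(loc, c(3, 7), max_lag = 20000,
                                             n_bins = 1))
  expect_equal(ev$gamma, (3 - 7)^2 / 2)
  expect_equal(ev$n_pairs, 1L)
})

test_that("zero-distance pairs feed the nugget evidence, not the bins", {
  loc <- cbind(c(500, 500, 20500, 40500), c(500, 500, 500, 500))
  suppressWarnings(ev <- empirical_variogram(loc, c(1, 2, 3, 4),
                                             max_lag = 50000, n_bins = 2))
  expect_equal(attr(ev, "nugget_pairs"), 1L)
  expect_equal(attr(ev, "nugget_gamma"), (1 - 2)^2 / 2)
  expect_equal(sum(ev$n_pairs), 5L)  # the 6th pair is the coincident one
})

test_that("pair counts partition all pairs within the max lag", {
  set.seed(14)
  loc <- random_locations(40)
  ev <- empirical_variogram(loc, rnorm(40), n_bins = 10)
  d <- as.vector(dist(loc))
  expect_equal(sum(ev$n_pairs), sum(d > 0 & d <= attr(ev, "max_lag")))
})

test_that("white noise produces a flat variogram at the noise variance", {
  set.seed(15)
  loc <- random_locations(400, extent = 500000)
  vals <- rnorm(400, 0, 0.5)
  ev <- empirical_variogram(loc, vals, n_bins = 8)
  expect_true(all(abs(ev$gamma - 0.25) < 0.05))
})

test_that("noise-free stable points are recovered to 1e-4 relative", {
  truth <- stable_variogram(0.30, 0.60, 120000, 1.3)
  h <- seq(10000, 250000, length.out = 12)
  ev <- data.frame(dist = h, mid = h, gamma = semivariance(truth, h),
                   n_pairs = rep(200L, 12), empty = FALSE)
  class(ev) <- c("empirical_variogram", "data.frame")
  fit <- fit_variogram(ev)
  expect_equal(fit$nugget, truth$nugget, tolerance = 1e-4)
  expect_equal(fit$psill, truth$psill, tolerance = 1e-4)
  expect_equal(fit$range, truth$range, tolerance = 1e-4)
  expect_equal(fit$shape, truth$shape, tolerance = 1e-4)
  # deterministic: a second run reproduces the parameters exactly
  fit2 <- fit_variogram(ev)
  expect_identical(unclass(fit)[1:4], unclass(fit2)[1:4])
})

test_that("fitted variograms are valid on accepted parameter sets", {
  set.seed(16)
  cfg <- isoscape_sim_config(n_samples = 300, variogram =
    stable_variogram(0.2, 0.5, 150000, 1.2), n_clusters = 40, seed = 21)
  sim <- simulate_isoscape(cfg)
  loc <- as.matrix(sim$samples[, c("easting", "northing")])
  tr <- fit_trend(loc, sim$samples$d18Op)
  ev <- empirical_variogram(loc, tr$residuals)
  fit <- fit_variogram(ev)
  h <- seq(1, 10 * fit$range, length.out = 500)
  g <- semivariance(fit, h)
  expect_true(all(diff(g) >= -1e-12))
  expect_true(all(g[h > 0] >= 0))
})
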