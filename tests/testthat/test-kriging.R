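vg_test <- stable_variogram(0.3, 0.6, 120000, 1.3)

test_that("declustering weights follow the cell rule and sum to n", {
  # all in distinct cells
  loc <- cbind(c(500, 100500, 200500), c(500, 500, 500))
  expect_equal(decluster_weights(loc, 50000), rep(1, 3))
  # 4 samples share a cell, 1 alone: weights 5/8 each and 5/2
  loc2 <- cbind(c(1, 2, 3, 4, 900000), c(1, 2, 3, 4, 900000))
  expect_equal(decluster_weights(loc2, 100000), c(rep(5 / 8, 4), 5 / 2))
  set.seed(17)
  loc3 <- random_locations(100)
  expect_equal(sum(decluster_weights(loc3, 20000)), 100)
})

test_that("a single neighbour receives the full weight", {
  kp <- krige_point(c(0, 0), cbind(50000, 0), residuals = 1.7, vg = vg_test)
  expect_equal(kp$weights, 1)
  expect_equal(kp$prediction, 1.7)
})

test_that("with no nugget the predictor interpolates exactly", {
  set.seed(18)
  vg0 <- stable_variogram(0, 0.6, 120000, 1.3)
  loc <- random_locations(12)
  z <- rnorm(12)
  for (i in c(1, 5, 12)) {
    kp <- krige_point(loc[i, ], loc, z, vg0)
    expect_equal(kp$prediction, z[i], tolerance = 1e-8)
    expect_lt(kp$variance, 1e-8)
  }
})

test_that("the solver matches the brute-force full-matrix oracle", {
  set.seed(19)
  for (rep in 1:200) {
    n <- sample(2:10, 1)
    loc <- random_locations(n)
    z <- rnorm(n)
    target <- runif(2, 0, 100000)
    kp <- krige_point(target, loc, z, vg_test)
    or <- krige_oracle(target, loc, z, vg_test)
    expect_equal(kp$prediction, or$prediction, tolerance = 1e-9)
    expect_equal(kp$variance, or$variance, tolerance = 1e-9)
    expect_equal(sum(kp$weights), 1, tolerance = 1e-10)
  }
})

test_that("predictions are translation-equivariant in value space", {
  set.seed(20)
  loc <- random_locations(15)
  z <- rnorm(15)
  t1 <- krige_point(c(5e4, 5e4), loc, z, vg_test)
  t2 <- krige_point(c(5e4, 5e4), loc, z + 5, vg_test)
  expect_equal(t2$prediction, t1$prediction + 5, tolerance = 1e-9)
  expect_equal(t2$variance, t1$variance, tolerance = 1e-9)
})

test_that("coincident samples keep the system solvable via the nugget", {
  loc <- cbind(c(500, 500, 40500), c(500, 500, 500))
  z <- c(1.0, 1.4, -0.5)
  kp <- krige_point(c(20500, 500), loc, z, vg_test)
  expect_true(is.finite(kp$prediction) && is.finite(kp$variance))
  expect_equal(sum(kp$weights), 1, tolerance = 1e-10)
})

test_that("the smoothed neighbourhood tapers but preserves unbiasedness", {
  set.seed(21)
  loc <- random_locations(40, extent = 200000)
  z <- rnorm(40)
  kp <- krige_point(c(1e5, 1e5), loc, z, vg_test,
                    neighbourhood = "smoothed", radius = 150000,
                    smoothing = 0.5)
  expect_equal(sum(kp$weights), 1, tolerance = 1e-10)
  d <- sqrt(rowSums((loc[kp$index, , drop = FALSE] -
                       rep(c(1e5, 1e5), each = length(kp$index)))^2))
  expect_true(all(d <= 150000))
})

test_that("grid kriging agrees with point kriging and a constant field", {
  set.seed(22)
  sim <- simulate_isoscape(isoscape_sim_config(n_samples = 60, seed = 5,
    domain = c(0, 2e5, 0, 2e5), n_clusters = 8))
  loc <- as.matrix(sim$samples[, c("easting", "northing")])
  vals <- sim$samples$d18Op
  tr <- fit_trend(loc, vals)
  surf <- krige_grid(loc, vals, tr, vg_test, cell_size = 50000)
  expect_true(all(surf$se >= 0))
  expect_equal(dim(surf$prediction), dim(surf$se))
  # a grid cell centre re-predicted as a point gives the same answer
  tgt <- c(surf$x[2], surf$y[3])
  kp <- krige_point(tgt, loc, detrend(vals, tr, loc), vg_test)
  expect_equal(surf$prediction[3, 2],
               unname(kp$prediction + predict_trend(tr, rbind(tgt))),
               tolerance = 1e-9)
  # constant residual field with no nugget -> constant surface
  vg0 <- stable_variogram(0, 0.6, 120000, 1.3)
  surf0 <- krige_grid(loc, predict_trend(tr, loc) + 2, tr, vg0,
                      cell_size = 50000)
  trend_grid <- matrix(predict_trend(tr, as.matrix(expand.grid(surf0$x, surf0$y))),
                       nrow = length(surf0$x))      # [x, y] column-major
  expect_equal(range(surf0$prediction - t(trend_grid)), c(2, 2),
               tolerance = 1e-6)
})

test_that("ESRI ASCII export round-trips through a text parse", {
  set.seed(23)
  sim <- simulate_isoscape(isoscape_sim_config(n_samples = 40, seed = 2,
    domain = c(0, 1e5, 0, 1e5), n_clusters = 5))
  loc <- as.matrix(sim$samples[, c("easting", "northing")])
  tr <- fit_trend(loc, sim$samples$d18Op)
  surf <- krige_grid(loc, sim$samples$d18Op, tr, vg_test, cell_size = 25000)
  f <- tempfile(fileext = ".asc")
  write_asc(surf, f)
  hdr <- readLines(f, n = 6)
  expect_match(hdr[1], "^ncols")
  vals <- scan(f, skip = 6, quiet = TRUE)
  expect_equal(length(vals), surf$n_rows * surf$n_cols)
  # first data row is the northernmost: matches the top prediction row
  expect_equal(vals[1:surf$n_cols], surf$prediction[surf$n_rows, ],
               tolerance = 1e-6)
})

test_that("leave-one-out CV predicts a coincident duplicate exactly when nugget is 0", {
  vg0 <- stable_variogram(0, 0.6, 120000, 1.3)
  set.seed(24)
  loc <- rbind(c(500, 500), c(500, 500), random_locations(10))
  z <- c(2.2, 2.2, rnorm(10))
  tr <- fit_trend(loc, z)
  tr$coefficients[] <- 0; tr$fitted[] <- 0; tr$residuals <- z
  # each duplicate predicts the other exactly; with zero kriging SE their
  # standardized errors are undefined, so they are flagged out of the summary
  expect_warning(cvr <- loo_cv(loc, z, tr, vg0), "no usable|excluded")
  expect_equal(cvr$records$error[1:2], c(0, 0), tolerance = 1e-8)
  expect_equal(cvr$summary$n, 10)
})
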