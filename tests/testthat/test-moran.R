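test_that("a rook-lattice checkerboard gives Moran's I of -1", {
  loc <- cbind(c(0, 1, 0, 1) * 1000, c(0, 0, 1, 1) * 1000)
  vals <- c(1, -1, -1, 1)   # every rook neighbour has the opposite value
  w <- build_weights(loc, threshold = 1000, idw_power = 1)
  m <- moran_test(vals, w)
  expect_equal(m$I, -1)
  expect_equal(m$expected, -1 / 3)
})

test_that("the matrix formulation equals the brute-force double sum", {
  set.seed(101)
  for (rep in 1:30) {
    n <- sample(6:30, 1)
    loc <- random_locations(n)
    w <- build_weights(loc, threshold = min_connecting_threshold(loc) * 1.5,
                       row_standardize = sample(c(TRUE, FALSE), 1))
    vals <- rnorm(n)
    expect_equal(moran_test(vals, w)$I, moran_brute(vals, w$W),
                 tolerance = 1e-12)
  }
})

test_that("permutation mean of I matches -1/(n-1)", {
  set.seed(7)
  n <- 40
  loc <- random_locations(n)
  w <- build_weights(loc, threshold = min_connecting_threshold(loc) * 1.2)
  vals <- rnorm(n)
  sims <- replicate(999, moran_test(sample(vals), w)$I)
  # 4-sigma Monte-Carlo band on the mean of 999 permutations
  expect_lt(abs(mean(sims) - (-1 / (n - 1))), 4 * sd(sims) / sqrt(999))
})

test_that("degenerate inputs are rejected", {
  loc <- random_locations(6)
  w <- build_weights(loc, threshold = 1e9)
  expect_error(moran_test(rep(2, 6), w), "zero variance")
  expect_error(local_moran(rep(2, 6), w), "zero variance")
})

test_that("local statistics sum to S0 times the global statistic", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(10:25, 1)
    loc <- random_locations(n)
    w <- build_weights(loc, threshold = min_connecting_threshold(loc) * 1.3,
                       row_standardize = sample(c(TRUE, FALSE), 1))
    vals <- rnorm(n)
    lm_ <- local_moran(vals, w, inference = "analytic")
    gl <- moran_test(vals, w)
    expect_equal(sum(lm_$Ii), gl$S0 * gl$I, tolerance = 1e-10)
  }
})

test_that("permutation p-values are invariant to shifting and rescaling", {
  set.seed(5)
  n <- 25
  loc <- random_locations(n)
  w <- build_weights(loc, threshold = min_connecting_threshold(loc) * 1.2)
  vals <- rnorm(n)
  p1 <- local_moran(vals, w, n_perm = 199, seed = 99)$p
  p2 <- local_moran(3 + 2 * vals, w, n_perm = 199, seed = 99)$p
  expect_identical(p1, p2)
})

test_that("cluster/outlier classes follow the sign structure", {
  set.seed(12)
  # two tight value-clusters far apart -> strong HH/LL; flip one value -> outlier
  loc <- rbind(cbind(runif(15, 0, 5000), runif(15, 0, 5000)),
               cbind(runif(15, 200000, 205000), runif(15, 0, 5000)))
  vals <- c(rnorm(15, 10, 0.1), rnorm(15, -10, 0.1))
  vals[1] <- -10   # a low value among highs: spatial outlier
  w <- build_weights(loc, threshold = 210000, idw_power = 1)
  lm_ <- local_moran(vals, w, inference = "analytic")
  expect_true(all(lm_$Ii[lm_$cluster %in% c("HH", "LL")] > 0))
  expect_true(all(lm_$Ii[lm_$cluster %in% c("HL", "LH")] < 0))
  expect_equal(as.character(lm_$cluster[1]), "LH")
  # NS only where not FDR-significant
  expect_true(all(lm_$p_adj[lm_$cluster != "NS"] <= 0.05))
})

test_that("Benjamini-Hochberg flags implement the step-up rule", {
  expect_equal(fdr_significant(c(0.01, 0.02, 0.03, 0.04, 0.20), 0.05),
               c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_true(all(fdr_significant(rep(0, 5))))
  expect_identical(fdr_significant(numeric(0)), logical(0))
  expect_error(fdr_significant(c(0.2, 1.4)), "0, 1")
  # monotone: anything below a significant p is significant
  set.seed(3)
  p <- runif(50)^2
  flags <- fdr_significant(p, 0.1)
  if (any(flags)) expect_true(all(flags[p <= max(p[flags])]))
})
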