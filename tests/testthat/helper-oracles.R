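# Shared fixtures and independent brute-force oracles.
# The oracles deliberately avoid the package's computational paths: Moran's I
# by an explicit double sum, ordinary kriging by assembling and solving the
# full bordered system with generic linear algebra.

random_locations <- function(n, extent = 100000) {
  cbind(easting = runif(n, 0, extent), northing = runif(n, 0, extent))
}

# Moran's I by explicit double loop over pairs.
moran_brute <- function(values, W) {
  n <- length(values)
  z <- values - mean(values)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + W[i, j] * z[i] * z[j]
  (n / sum(W)) * num / sum(z^2)
}

# Ordinary kriging oracle: full bordered semivariance system, generic solve.
# Mirrors the mathematical definition, not the package implementation.
krige_oracle <- function(target, loc, z, vg) {
  n <- nrow(loc)
  G <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) {
      h <- sqrt(sum((loc[i, ] - loc[j, ])^2))
      G[i, j] <- vg$nugget + vg$psill * (1 - exp(-3 * (h / vg$range)^vg$shape))
    }
  }
  g0 <- numeric(n)
  for (i in seq_len(n)) {
    h <- sqrt(sum((loc[i, ] - target)^2))
    g0[i] <- vg$nugget + vg$psill * (1 - exp(-3 * (h / vg$range)^vg$shape))
  }
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  sol <- solve(A, c(g0, 1))
  lambda <- sol[1:n]
  list(prediction = sum(lambda * z),
       variance = sum(lambda * g0) + sol[n + 1],
       weights = lambda)
}

# small well-formed sample table on disk, returned as a path
write_toy_table <- function(path = tempfile(fileext = ".csv")) {
  df <- data.frame(
    sample_id = c("SK001", "SK002", "SK003"),
    site_name = c("Woodhenge", "Bee Low", "Staxton"),
    region_code = c(13L, 8L, 7L),
    ngr = c("SU1543", "SK1964", "TA0179"),
    easting = NA, northing = NA,
    d18Op = c(18.2, 17.5, 16.9),
    sd = c(0.1, 0.15, 0.1),
    n_replicates = c(3L, 2L, 3L),
    period_ok = c(TRUE, TRUE, FALSE))
  write.csv(df, path, row.names = FALSE, na = "")
  path
}
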