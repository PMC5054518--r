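#' Global Moran's I test of spatial autocorrelation
#'
#' Computes Moran's I for a variable observed at the locations underlying a
#' [build_weights()] object, with inference under the randomization
#' (permutation-moment) assumption: the null mean is `-1/(n-1)` and the
#' null variance uses the standard randomization formula with the sample
#' kurtosis, giving a normal z-score and two-sided p-value.
#'
#' @param values numeric vector, one value per sample (must have positive
#'   variance; `n >= 4`).
#' @param weights a `spatial_weights` object.
#' @return A list of class `moran_test`: `I`, `expected`, `variance`, `z`,
#'   `p`, `n`, `S0`.
#' @export
moran_test <- function(values, weights) {
  stopifnot(inherits(weights, "spatial_weights"))
  W <- weights$W
  n <- length(values)
  if (n != nrow(W)) stop("values and weights disagree on n")
  if (n < 4L) stop("need n >= 4 for randomization inference")
  z <- values - mean(values)
  m2sum <- sum(z^2)
  if (m2sum == 0) stop("values have zero variance")
  S0 <- sum(W)
  I <- (n / S0) * drop(crossprod(z, W %*% z)) / m2sum
  EI <- -1 / (n - 1)
  S1 <- 0.5 * sum((W + t(W))^2)
  S2 <- sum((rowSums(W) + colSums(W))^2)
  b2 <- n * sum(z^4) / m2sum^2
  VarI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
             b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
  zscore <- (I - EI) / sqrt(VarI)
  p <- 2 * stats::pnorm(-abs(zscore))
  structure(list(I = I, expected = EI, variance = VarI, z = zscore, p = p,
                 n = n, S0 = S0),
            class = "moran_test")
}

#' @export
print.moran_test <- function(x, ...) {
  cat(sprintf("Global Moran's I = %.3f (expected %.3f)\n", x$I, x$expected))
  cat(sprintf("z = %.3f, p = %.3g (randomization assumption, two-sided)\n",
              x$z, x$p))
  invisible(x)
}

#' Anselin's Local Moran's I with FDR-controlled cluster/outlier classes
#'
#' Computes the local Moran statistic `I_i = (z_i / m2) * sum_j w_ij z_j`
#' (`m2 = sum(z^2)/n`) for every sample, with either conditional-permutation
#' inference (default; one-sided pseudo p-values `(k+1)/(n_perm+1)`) or
#' analytic inference from the exact conditional-permutation moments.
#' P-values are Benjamini-Hochberg adjusted and significant samples are
#' classified by the signs of their own deviation and of their spatial lag:
#' `HH`/`LL` are cluster cores (value like its neighbours), `HL`/`LH` are
#' spatial outliers (value unlike its neighbours); non-significant samples
#' are `NS`.
#'
#' @inheritParams moran_test
#' @param inference `"permutation"` (default) or `"analytic"`.
#' @param n_perm number of conditional permutations (>= 99).
#' @param seed integer seed for the permutations (RNG state is restored).
#' @param alpha FDR level for the classification, default 0.05.
#' @return A data frame of class `local_moran`: `Ii`, `expected`, `z`
#'   (score), `p`, `p_adj`, `lag` (row-standardized spatial lag of the
#'   deviations), `cluster` (factor HH/LL/HL/LH/NS).
#' @references Anselin, L. (1995) Local indicators of spatial association.
#' @export
local_moran <- function(values, weights,
                        inference = c("permutation", "analytic"),
                        n_perm = 999, seed = NULL, alpha = 0.05) {
  stopifnot(inherits(weights, "spatial_weights"))
  inference <- match.arg(inference)
  W <- weights$W
  n <- length(values)
  if (n != nrow(W)) stop("values and weights disagree on n")
  z <- values - mean(values)
  m2 <- sum(z^2) / n
  if (m2 == 0) stop("values have zero variance")
  lag <- drop(W %*% z)
  Ii <- z * lag / m2

  Wi <- rowSums(W)      # total weight per row
  Si2 <- rowSums(W^2)
  # exact moments of the lag under conditional permutation of the other n-1
  # values: neighbours receive a simple random sample without replacement
  mbar <- -z / (n - 1)
  ssq <- (sum(z^2) - z^2) / (n - 1) - mbar^2   # population variance of the rest
  Elag <- Wi * mbar
  Vlag <- ssq * (Si2 - (Wi^2 - Si2) / (n - 2))
  EIi <- z * Elag / m2
  VIi <- (z / m2)^2 * Vlag
  score <- (Ii - EIi) / sqrt(pmax(VIi, .Machine$double.xmin))

  if (inference == "analytic") {
    p <- 2 * stats::pnorm(-abs(score))
  } else {
    if (n_perm < 99) stop("n_perm must be >= 99")
    p <- with_seed(seed, {
      pv <- numeric(n)
      for (i in seq_len(n)) {
        wj <- W[i, -i]
        nb <- which(wj > 0)
        if (!length(nb)) { pv[i] <- NA_real_; next }
        rest <- z[-i]
        k <- length(nb)
        wnb <- wj[nb]
        sims <- vapply(seq_len(n_perm),
                       function(p_) sum(wnb * sample(rest, k)), numeric(1))
        sims <- z[i] * sims / m2
        extreme <- if (Ii[i] >= EIi[i]) sum(sims >= Ii[i]) else sum(sims <= Ii[i])
        pv[i] <- (extreme + 1) / (n_perm + 1)
      }
      pv
    })
  }
  p_adj <- stats::p.adjust(p, method = "BH")
  sig <- !is.na(p_adj) & p_adj <= alpha
  cl <- rep("NS", n)
  cl[sig & z > 0 & lag > 0] <- "HH"
  cl[sig & z < 0 & lag < 0] <- "LL"
  cl[sig & z > 0 & lag < 0] <- "HL"
  cl[sig & z < 0 & lag > 0] <- "LH"
  out <- data.frame(Ii = Ii, expected = EIi, z = score, p = p, p_adj = p_adj,
                    lag = lag,
                    cluster = factor(cl, levels = c("HH", "LL", "HL", "LH", "NS")))
  attr(out, "inference") <- inference
  attr(out, "alpha") <- alpha
  class(out) <- c("local_moran", "data.frame")
  out
}

#' Benjamini-Hochberg significance flags
#'
#' Step-up false-discovery-rate control: flags are `TRUE` for the p-values
#' kept at level `alpha`, and are monotone in p (anything smaller than a
#' significant p-value is also significant).
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @param alpha FDR level.
#' @return logical vector of the same length.
#' @export
fdr_significant <- function(pvalues, alpha = 0.05) {
  if (!length(pvalues)) return(logical(0))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH") <= alpha
}
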