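#' Stable semivariogram model
#'
#' The stable (powered-exponential) family
#' \deqn{\gamma(h) = c_0 + c\,(1 - e^{-3 (h/r)^\omega}), \quad h > 0;\qquad \gamma(0) = 0,}
#' with nugget `c0`, partial sill `c`, range `r` (metres) and shape
#' `omega` in (0, 2]. The factor 3 implements the *practical range*
#' convention: the semivariance reaches about 95% of the sill at `h = r`,
#' matching the convention of the GIS software family in which such
#' parameters are usually reported (other conventions omit the 3; rescale
#' `r` accordingly when importing parameters). `omega = 1` gives the
#' exponential model and `omega = 2` the Gaussian model.
#'
#' @param nugget micro-scale/measurement variance `c0 >= 0`, (permil)^2.
#' @param psill partial sill `c >= 0`, (permil)^2.
#' @param range practical range `r > 0`, metres.
#' @param shape exponent `omega` in (0, 2], default 1.
#' @return A `variogram_model` object.
#' @examples
#' vg <- stable_variogram(0.299684, 0.015628, 121384.818021, 1.170313)
#' semivariance(vg, vg$range)  # c0 + c * (1 - exp(-3))
#' @export
stable_variogram <- function(nugget, psill, range, shape = 1) {
  stopifnot(nugget >= 0, psill >= 0, range > 0, shape > 0, shape <= 2)
  nugget <- unname(nugget); psill <- unname(psill)
  range <- unname(range); shape <- unname(shape)
  structure(list(nugget = nugget, psill = psill, range = range, shape = shape,
                 model = "stable"),
            class = "variogram_model")
}

#' @rdname stable_variogram
#' @param vg a `variogram_model`.
#' @param h distances in metres.
#' @export
semivariance <- function(vg, h) {
  stopifnot(inherits(vg, "variogram_model"), all(h >= 0))
  g <- sv_distinct(vg, h)
  g[h == 0] <- 0
  g
}

# semivariance between DISTINCT measurements: the nugget (micro-scale +
# measurement error) applies even at h = 0, so coincident samples are kept
# as separate, mutually informative equations.
sv_distinct <- function(vg, h) {
  vg$nugget + vg$psill * (1 - exp(-3 * (h / vg$range)^vg$shape))
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf(
    "Stable semivariogram: nugget = %.6g, partial sill = %.6g,\n  range = %.6g m, shape = %.6g (sill = %.6g)\n",
    x$nugget, x$psill, x$range, x$shape, x$nugget + x$psill))
  invisible(x)
}

#' Empirical semivariogram (Matheron estimator)
#'
#' Bins sample pairs by separation distance and computes
#' `gamma_hat(h) = sum (z_i - z_j)^2 / (2 N(h))` per bin. Pairs at exactly
#' zero distance (coincident grid squares) are *not* mixed into the first
#' bin: their mean squared half-difference is reported separately as
#' direct evidence about the nugget.
#'
#' @param locations two-column matrix, metres.
#' @param residuals numeric vector (typically detrended values).
#' @param max_lag largest pair distance used, metres; default half the
#'   maximum pairwise distance.
#' @param n_bins number of equal-width bins, default 12.
#' @return A data frame of class `empirical_variogram` with columns `dist`
#'   (mean pair distance per bin), `mid` (bin midpoint), `gamma`, `n_pairs`,
#'   `empty` (bin had no pairs); attributes `nugget_pairs`/`nugget_gamma`
#'   summarise zero-distance pairs, `max_lag` and `n` are recorded.
#' @export
empirical_variogram <- function(locations, residuals, max_lag = NULL, n_bins = 12) {
  loc <- stop_if_not_coords(locations)
  n <- nrow(loc)
  stopifnot(length(residuals) == n, n_bins >= 1)
  if (n < 2L) stop("need at least 2 samples")
  if (n < 20L)
    warning("fewer than 20 samples: empirical semivariances will be noisy")
  D <- stats::dist(loc)
  dz2 <- stats::dist(residuals)^2
  d <- as.vector(D)
  g <- as.vector(dz2) / 2
  if (is.null(max_lag)) max_lag <- max(d) / 2
  stopifnot(max_lag > 0)
  zero <- d == 0
  nugget_pairs <- sum(zero)
  nugget_gamma <- if (nugget_pairs) mean(g[zero]) else NA_real_
  keep <- !zero & d <= max_lag
  breaks <- seq(0, max_lag, length.out = n_bins + 1L)
  bin <- cut(d[keep], breaks, include.lowest = TRUE, labels = FALSE)
  gamma <- tapply(g[keep], factor(bin, levels = seq_len(n_bins)), mean)
  dmean <- tapply(d[keep], factor(bin, levels = seq_len(n_bins)), mean)
  npairs <- tabulate(bin, nbins = n_bins)
  out <- data.frame(dist = as.numeric(dmean),
                    mid = (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2,
                    gamma = as.numeric(gamma),
                    n_pairs = npairs,
                    empty = npairs == 0L)
  attr(out, "nugget_pairs") <- nugget_pairs
  attr(out, "nugget_gamma") <- nugget_gamma
  attr(out, "max_lag") <- max_lag
  attr(out, "n") <- n
  class(out) <- c("empirical_variogram", "data.frame")
  out
}

#' Fit a stable model to an empirical semivariogram
#'
#' Weighted least squares with fixed weights `n_pairs / gamma_hat^2`
#' (down-weighting sparse and high-variance bins), over the box
#' `c0, c >= 0`, `r > 0`, `omega` in (0, 2]. The fit profiles out the two
#' linear parameters: for any `(r, omega)` the optimal `(c0, c)` is a
#' non-negative weighted linear least-squares solution, so the optimizer
#' only searches the 2-dimensional `(log r, omega)` space — a coarse grid
#' followed by Nelder-Mead polishing. Deterministic for given data.
#'
#' @param ev an [empirical_variogram()] (>= 4 usable bins).
#' @param shape_bounds permitted `omega` interval, default `c(0.05, 2)`.
#' @param init optional `variogram_model` used as the starting point
#'   (otherwise an automatic initial guess plus grid search).
#' @return A `variogram_model` with attributes `objective` (attained WLS
#'   value) and `convergence`.
#' @export
fit_variogram <- function(ev, shape_bounds = c(0.05, 2), init = NULL) {
  stopifnot(inherits(ev, "empirical_variogram"))
  use <- !ev$empty & is.finite(ev$gamma) & ev$gamma > 0
  if (sum(use) < 4L) stop("need at least 4 non-empty variogram bins")
  h <- ev$dist[use]
  ghat <- ev$gamma[use]
  w <- ev$n_pairs[use] / ghat^2

  profile_fit <- function(logr, om) {
    r <- exp(logr)
    gshape <- 1 - exp(-3 * (h / r)^om)
    # weighted LS in (c0, c) with non-negativity: try full, then boundary fits
    X <- cbind(1, gshape)
    XtWX <- crossprod(X, w * X)
    XtWy <- crossprod(X, w * ghat)
    cand <- list()
    sol <- tryCatch(drop(solve(XtWX, XtWy)), error = function(e) NULL)
    if (!is.null(sol) && all(sol >= 0)) cand <- c(cand, list(sol))
    c_only <- sum(w * gshape * ghat) / sum(w * gshape^2)
    cand <- c(cand, list(c(0, max(c_only, 0))))
    c0_only <- sum(w * ghat) / sum(w)
    cand <- c(cand, list(c(max(c0_only, 0), 0)))
    best <- NULL; bobj <- Inf
    for (p in cand) {
      obj <- sum(w * (ghat - p[1L] - p[2L] * gshape)^2)
      if (obj < bobj) { bobj <- obj; best <- p }
    }
    list(c0 = best[1L], c = best[2L], obj = bobj)
  }
  objective <- function(par) {
    om <- min(max(par[2L], shape_bounds[1L]), shape_bounds[2L])
    pen <- 1e6 * (abs(par[2L] - om))^2
    profile_fit(par[1L], om)$obj * (1 + pen)
  }

  if (!is.null(init)) {
    stopifnot(inherits(init, "variogram_model"))
    starts <- list(c(log(init$range), init$shape))
  } else {
    rg <- exp(seq(log(min(h[h > 0]) / 2), log(max(h) * 4), length.out = 30))
    og <- seq(shape_bounds[1L], shape_bounds[2L], length.out = 14)
    grid <- expand.grid(logr = log(rg), om = og)
    vals <- mapply(function(lr, om) profile_fit(lr, om)$obj, grid$logr, grid$om)
    ord <- order(vals)[1:3]
    starts <- lapply(ord, function(i) c(grid$logr[i], grid$om[i]))
  }
  best <- NULL
  for (s in starts) {
    opt <- stats::optim(s, objective, method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 5000))
    opt <- stats::optim(opt$par, objective, method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 5000))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  om <- min(max(best$par[2L], shape_bounds[1L]), shape_bounds[2L])
  pf <- profile_fit(best$par[1L], om)
  out <- stable_variogram(nugget = pf$c0, psill = pf$c,
                          range = exp(best$par[1L]), shape = om)
  attr(out, "objective") <- pf$obj
  attr(out, "convergence") <- best$convergence
  out
}
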