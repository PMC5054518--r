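#' Polynomial trend surface fitting and removal
#'
#' Fits a 2nd-order (default) polynomial trend surface to isotope values by
#' (optionally weighted) ordinary least squares on the 6-term design
#' `1, x, y, x^2, xy, y^2`. Coordinates are standardized (centred and
#' scaled per axis) before fitting to keep the design well conditioned at
#' the 1e5-1e6 m magnitudes of national-grid coordinates; the scaling is
#' stored with the coefficients so the surface can be evaluated anywhere.
#' Declustering weights (see [decluster_weights()]) may be supplied so
#' preferentially sampled areas do not dominate the trend.
#'
#' @param locations two-column matrix of easting/northing in metres.
#' @param values numeric vector of per-mil values.
#' @param order polynomial order, 1 or 2 (default 2).
#' @param weights optional non-negative case weights.
#' @param centre,scale optional per-axis standardization to use instead of
#'   the data mean/SD (useful to express coefficients in an externally
#'   fixed parameterization, e.g. a simulation's domain coordinates).
#' @return A `trend_surface` object with `coefficients` (named beta0..beta5),
#'   their standard errors (`se`), `centre`, `scale`, `order`, `fitted` and
#'   `residuals`.
#' @export
fit_trend <- function(locations, values, order = 2, weights = NULL,
                      centre = NULL, scale = NULL) {
  loc <- stop_if_not_coords(locations)
  stopifnot(order %in% 1:2, length(values) == nrow(loc))
  n <- nrow(loc)
  if (n < 10L) stop("need at least 10 locations for a stable trend fit")
  if (is.null(centre)) centre <- colMeans(loc)
  if (is.null(scale)) {
    scale <- apply(loc, 2L, stats::sd)
    scale[scale == 0] <- 1
  }
  X <- trend_design(loc, centre, scale, order)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient trend design (collinear locations)")
  w <- if (is.null(weights)) rep(1, n) else weights
  stopifnot(length(w) == n, all(w >= 0))
  fit <- stats::lm.wfit(X, values, w)
  beta <- fit$coefficients
  fitted <- drop(X %*% beta)
  resid <- values - fitted
  p <- ncol(X)
  sigma2 <- sum(w * resid^2) / (n - p)
  XtWX_inv <- chol2inv(chol(crossprod(X, w * X)))
  se <- sqrt(pmax(diag(XtWX_inv) * sigma2, 0))
  names(se) <- names(beta)
  structure(list(coefficients = beta, se = se, centre = centre, scale = scale,
                 order = order, fitted = fitted,
                 residuals = resid, n = n),
            class = "trend_surface")
}

trend_design <- function(loc, centre, scl, order) {
  x <- (loc[, 1L] - centre[1L]) / scl[1L]
  y <- (loc[, 2L] - centre[2L]) / scl[2L]
  X <- cbind(beta0 = 1, beta1_x = x, beta2_y = y)
  if (order == 2L) X <- cbind(X, beta3_x2 = x^2, beta4_xy = x * y, beta5_y2 = y^2)
  X
}

#' @rdname fit_trend
#' @param trend a `trend_surface` object.
#' @export
predict_trend <- function(trend, locations) {
  stopifnot(inherits(trend, "trend_surface"))
  loc <- stop_if_not_coords(locations)
  X <- trend_design(loc, trend$centre, trend$scale, trend$order)
  drop(X %*% trend$coefficients)
}

#' @rdname fit_trend
#' @details `detrend()` subtracts the evaluated trend from values;
#'   `retrend()` adds it back, so `retrend(detrend(v))` is the identity at
#'   machine precision. The trend is treated as deterministic: kriging is
#'   carried out on detrended residuals and the trend added back to the
#'   predictions.
#' @export
detrend <- function(values, trend, locations) {
  values - predict_trend(trend, locations)
}

#' @rdname fit_trend
#' @export
retrend <- function(values, trend, locations) {
  values + predict_trend(trend, locations)
}

#' @export
print.trend_surface <- function(x, ...) {
  cat(sprintf("Polynomial trend surface (order %d, n = %d)\n", x$order, x$n))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.trend_surface <- function(object, ...) object$coefficients

#' @export
residuals.trend_surface <- function(object, ...) object$residuals
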