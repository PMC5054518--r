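#' Fit a geostatistical isoscape model
#'
#' The central model of the package: given point-located isotope values it
#' (1) computes cell-declustering weights to offset preferential sampling,
#' (2) fits a 2nd-order polynomial trend surface by declustered weighted
#' least squares, (3) estimates the empirical semivariogram of the
#' detrended residuals, and (4) fits a stable semivariogram model (or
#' accepts fixed parameters, e.g. values published from another software's
#' optimiser). The returned object predicts by ordinary kriging of the
#' residuals with the trend added back, and supports `print`, `summary`
#' (leave-one-out cross-validation), `coef`, `predict`, `residuals`,
#' `simulate` and `plot` methods.
#'
#' @param data an `isotope_samples` data frame (see [read_samples()]), or
#'   any data frame with the `coords` and `value` columns.
#' @param value name of the value column (permil), default `"d18Op"`.
#' @param coords names of the easting/northing columns (metres).
#' @param trend_order polynomial trend order, default 2.
#' @param variogram `"fit"` (default: estimate from the residuals) or a
#'   [stable_variogram()] to use as-is.
#' @param decluster_cell declustering cell side, metres (default 50 km);
#'   `NULL` disables declustering.
#' @param max_lag,n_bins empirical-variogram controls (see
#'   [empirical_variogram()]).
#' @param neighbourhood kriging neighbourhood, `"global"` (default) or
#'   `"smoothed"`.
#' @param smoothing smoothing factor for the smoothed neighbourhood.
#' @return An object of class `isoscape`.
#' @examples
#' sim <- simulate_isoscape(isoscape_sim_config(n_samples = 120, seed = 7))
#' fit <- isoscape(sim$samples)
#' fit
#' coef(fit)
#' @export
isoscape <- function(data, value = "d18Op", coords = c("easting", "northing"),
                     trend_order = 2, variogram = "fit",
                     decluster_cell = 50000, max_lag = NULL, n_bins = 12,
                     neighbourhood = c("global", "smoothed"), smoothing = 0.5) {
  stopifnot(is.data.frame(data), value %in% names(data),
            all(coords %in% names(data)))
  neighbourhood <- match.arg(neighbourhood)
  loc <- as.matrix(data[, coords])
  colnames(loc) <- c("easting", "northing")
  loc <- stop_if_not_coords(loc)
  z <- data[[value]]
  stopifnot(is.numeric(z), all(is.finite(z)))
  ids <- if ("sample_id" %in% names(data)) as.character(data$sample_id)
         else as.character(seq_len(nrow(data)))

  dw <- if (is.null(decluster_cell)) rep(1, nrow(loc))
        else decluster_weights(loc, decluster_cell)
  trend <- fit_trend(loc, z, order = trend_order, weights = dw)
  res <- detrend(z, trend, loc)
  ev <- empirical_variogram(loc, res, max_lag = max_lag, n_bins = n_bins)
  if (identical(variogram, "fit")) {
    vg <- fit_variogram(ev)
    vg_source <- "fitted"
  } else {
    stopifnot(inherits(variogram, "variogram_model"))
    vg <- variogram
    vg_source <- "fixed"
  }
  structure(list(locations = loc, values = z, ids = ids,
                 decluster = dw, trend = trend, residuals_trend = res,
                 empirical = ev, variogram = vg, vg_source = vg_source,
                 neighbourhood = neighbourhood, smoothing = smoothing,
                 call = match.call()),
            class = "isoscape")
}

#' @export
print.isoscape <- function(x, ...) {
  cat(sprintf("Isoscape model: %d samples, order-%d trend, %s stable variogram\n",
              length(x$values), x$trend$order, x$vg_source))
  print(x$variogram)
  cat(sprintf("kriging neighbourhood: %s\n", x$neighbourhood))
  invisible(x)
}

#' @export
coef.isoscape <- function(object, ...) {
  c(object$trend$coefficients,
    nugget = object$variogram$nugget, psill = object$variogram$psill,
    range = object$variogram$range, shape = object$variogram$shape)
}

#' Predict from an isoscape model
#'
#' With `newdata` (a data frame or matrix of easting/northing), returns
#' point predictions with kriging standard errors. Without `newdata`,
#' krige a whole [krige_grid()] surface over the sample bounding box.
#'
#' @param object an [isoscape()] fit.
#' @param newdata optional matrix/data frame of target coordinates.
#' @param cell_size grid cell size in metres when kriging a surface.
#' @param bbox optional bounding box for the surface.
#' @param ... unused.
#' @return A data frame (`easting`, `northing`, `prediction`, `se`) for
#'   point targets, else a `kriging_surface`.
#' @export
predict.isoscape <- function(object, newdata = NULL, cell_size = 5000,
                             bbox = NULL, ...) {
  if (is.null(newdata)) {
    return(krige_grid(object$locations, object$values, object$trend,
                      object$variogram, cell_size = cell_size, bbox = bbox,
                      neighbourhood = object$neighbourhood,
                      smoothing = object$smoothing))
  }
  tg <- as.matrix(as.data.frame(newdata)[, 1:2])
  tg <- stop_if_not_coords(tg)
  kr <- krige_points(tg, object$locations, object$residuals_trend,
                     object$variogram, object$neighbourhood,
                     radius = NULL, smoothing = object$smoothing)
  data.frame(easting = tg[, 1L], northing = tg[, 2L],
             prediction = retrend(kr$prediction, object$trend, tg),
             se = sqrt(kr$variance))
}

#' Leave-one-out cross-validation of an isoscape model
#'
#' @param object an [isoscape()] fit.
#' @return a `kriging_cv` object (see [loo_cv()]).
#' @export
cv <- function(object) UseMethod("cv")

#' @rdname cv
#' @export
cv.isoscape <- function(object) {
  loo_cv(object$locations, object$values, object$trend, object$variogram,
         neighbourhood = object$neighbourhood, smoothing = object$smoothing,
         ids = object$ids)
}

#' @export
residuals.isoscape <- function(object, type = c("cv", "trend"), ...) {
  type <- match.arg(type)
  if (type == "trend") return(object$residuals_trend)
  cv(object)$records$error
}

#' @export
summary.isoscape <- function(object, residual_threshold = 0.6,
                             residual_bin = 0.3, ...) {
  cvr <- cv(object)
  cls <- classify_residuals(cvr$records$error, threshold = residual_threshold,
                            bin = residual_bin)
  out <- list(n = length(object$values),
              values = isotope_summary(object$values),
              variogram = object$variogram, vg_source = object$vg_source,
              trend_coefficients = object$trend$coefficients,
              cv = cvr, residual_classes = table(cls$class),
              residual_threshold = residual_threshold)
  class(out) <- "summary.isoscape"
  out
}

#' @export
print.summary.isoscape <- function(x, ...) {
  cat("Isoscape model summary\n----------------------\n")
  print(x$values)
  print(x$variogram)
  print(x$cv)
  cat(sprintf("residual classes at %.1f permil threshold: %s\n",
              x$residual_threshold,
              paste(names(x$residual_classes), as.integer(x$residual_classes),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Simulate datasets from a fitted isoscape
#'
#' Draws new value vectors at the fitted sample locations from the model's
#' own generative form: fitted trend + Gaussian field with the fitted
#' stable covariance + independent nugget noise. Useful for parametric
#' bootstrap checks of downstream decisions.
#'
#' @param object an [isoscape()] fit.
#' @param nsim number of replicate datasets.
#' @param seed integer seed (RNG state restored afterwards).
#' @param ... unused.
#' @return numeric matrix `n x nsim`.
#' @export
simulate.isoscape <- function(object, nsim = 1, seed = NULL, ...) {
  cfg <- isoscape_sim_config(
    n_samples = length(object$values),
    domain = c(range(object$locations[, 1L]) + c(-1, 1),
               range(object$locations[, 2L]) + c(-1, 1)),
    variogram = object$variogram, seed = if (is.null(seed)) 1 else seed)
  cfg$trend <- object$trend
  out <- matrix(NA_real_, length(object$values), nsim)
  for (k in seq_len(nsim)) {
    cfg$seed <- (if (is.null(seed)) 1 else seed) + k - 1
    out[, k] <- simulate_field(object$locations, cfg)
  }
  out
}

#' @export
plot.isoscape <- function(x, which = 1, ...) {
  if (1 %in% which) {
    ev <- x$empirical
    use <- !ev$empty
    plot(ev$dist[use] / 1000, ev$gamma[use], pch = 16,
         xlab = "lag distance (km)", ylab = "semivariance",
         main = "Empirical and fitted semivariogram",
         ylim = c(0, max(ev$gamma[use], x$variogram$nugget + x$variogram$psill) * 1.1), ...)
    hh <- seq(1, max(ev$dist[use]), length.out = 200)
    graphics::lines(hh / 1000, semivariance(x$variogram, hh), col = "firebrick", lwd = 2)
  }
  if (2 %in% which) {
    surf <- predict(x, cell_size = max(diff(range(x$locations[, 1L])) / 80, 1000))
    graphics::image(surf$x / 1000, surf$y / 1000, t(surf$prediction),
                    xlab = "easting (km)", ylab = "northing (km)",
                    main = "Kriged isoscape", col = grDevices::hcl.colors(24, "viridis"))
    graphics::points(x$locations[, 1L] / 1000, x$locations[, 2L] / 1000,
                     pch = 16, cex = 0.4)
  }
  invisible(x)
}
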