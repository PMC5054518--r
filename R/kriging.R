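#' Cell-declustering weights
#'
#' Compensates for preferential (clustered) sampling: the domain is divided
#' into square cells of side `cell_size` and each sample receives weight
#' proportional to `1 / (number of samples in its cell)`, normalized so the
#' weights sum to `n`. Samples alone in a cell keep relatively large
#' weights; dense clusters share theirs.
#'
#' @param locations two-column matrix, metres.
#' @param cell_size cell side length in metres (> 0).
#' @return numeric weight vector summing to `nrow(locations)`.
#' @export
decluster_weights <- function(locations, cell_size) {
  loc <- stop_if_not_coords(locations)
  stopifnot(cell_size > 0)
  cell <- paste(floor(loc[, 1L] / cell_size), floor(loc[, 2L] / cell_size))
  counts <- table(cell)
  w <- 1 / as.numeric(counts[cell])
  w * nrow(loc) / sum(w)
}

# Semivariance matrix between two location sets for DISTINCT measurements.
sv_cross <- function(vg, loc_a, loc_b) {
  a2 <- rowSums(loc_a^2)
  b2 <- rowSums(loc_b^2)
  d2 <- outer(a2, b2, "+") - 2 * loc_a %*% t(loc_b)
  sv_distinct(vg, sqrt(pmax(d2, 0)))
}

# Ordinary-kriging left-hand side on the sample set: semivariances between
# distinct measurements off the diagonal (nugget applies at h = 0 between
# coincident samples), zeros on the diagonal, bordered by the unbiasedness
# constraint.
ok_lhs <- function(vg, loc) {
  n <- nrow(loc)
  G <- sv_cross(vg, loc, loc)
  diag(G) <- 0
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  A
}

#' Ordinary-kriging point prediction
#'
#' Solves the ordinary-kriging system
#' `[Gamma 1; 1' 0] [lambda; mu] = [gamma0; 1]` on the supplied samples,
#' where `Gamma` holds semivariances between distinct measurements (zero
#' diagonal; the nugget applies between coincident samples) and `gamma0`
#' the semivariances from each sample to the target. The prediction is
#' `sum(lambda * z)` and the kriging variance `sum(lambda * gamma0) + mu`.
#'
#' Neighbourhood modes: `"global"` (default) uses every sample —
#' exact and simple at the few-hundred-sample scale this package targets.
#' `"smoothed"` restricts to samples within `radius` of the target and
#' tapers the solved weights (full weight inside `smoothing * radius`,
#' linearly down to zero at `radius`, then renormalized to sum to 1), a
#' documented approximation of smoothed search neighbourhoods in
#' geostatistical GIS software.
#'
#' @param target length-2 numeric (easting, northing), metres.
#' @param locations two-column sample location matrix, metres.
#' @param residuals detrended sample values.
#' @param vg a `variogram_model`.
#' @param neighbourhood `"global"` or `"smoothed"`.
#' @param radius search radius for the smoothed mode, metres; default the
#'   variogram range.
#' @param smoothing smoothing factor in `[0, 1)` for the smoothed mode.
#' @return list with `prediction`, `variance`, `weights`, `mu`, `index`
#'   (sample indices used).
#' @export
krige_point <- function(target, locations, residuals, vg,
                        neighbourhood = c("global", "smoothed"),
                        radius = NULL, smoothing = 0.5) {
  neighbourhood <- match.arg(neighbourhood)
  loc <- stop_if_not_coords(locations)
  stopifnot(length(target) == 2L, length(residuals) == nrow(loc))
  res <- krige_points(matrix(target, nrow = 1L), loc, residuals, vg,
                      neighbourhood, radius, smoothing, keep_weights = TRUE)
  list(prediction = res$prediction[1L], variance = res$variance[1L],
       weights = res$weights[[1L]], mu = res$mu[1L], index = res$index[[1L]])
}

# Vectorized kriging of many targets. Global mode factors the (n+1) system
# once and back-solves for all targets simultaneously.
krige_points <- function(targets, loc, residuals, vg,
                         neighbourhood = "global", radius = NULL,
                         smoothing = 0.5, keep_weights = FALSE) {
  # with a zero nugget, exactly coincident samples make the system singular;
  # the coincidence rule collapses them to their mean (they must agree in the
  # noise-free model), keeping exact interpolation well defined
  key <- paste(loc[, 1L], loc[, 2L])
  if (vg$nugget == 0 && anyDuplicated(key)) {
    grp <- match(key, unique(key))
    residuals <- drop(rowsum(residuals, grp)) / tabulate(grp)
    loc <- loc[!duplicated(key), , drop = FALSE]
  }
  n <- nrow(loc)
  m <- nrow(targets)
  if (n < 1L) stop("need at least one sample")
  if (neighbourhood == "global") {
    A <- ok_lhs(vg, loc)
    G0 <- rbind(t(sv_cross(vg, targets, loc)), 1)   # (n+1) x m
    sol <- solve(A, G0)
    lambda <- sol[seq_len(n), , drop = FALSE]
    mu <- sol[n + 1L, ]
    pred <- drop(crossprod(lambda, residuals))
    varr <- colSums(lambda * G0[seq_len(n), , drop = FALSE]) + mu
    idx <- if (keep_weights) replicate(m, seq_len(n), simplify = FALSE) else NULL
    wts <- if (keep_weights) lapply(seq_len(m), function(j) lambda[, j]) else NULL
  } else {
    if (is.null(radius)) radius <- vg$range
    stopifnot(radius > 0, smoothing >= 0, smoothing < 1)
    pred <- varr <- mu <- numeric(m)
    wts <- idx <- vector("list", m)
    for (j in seq_len(m)) {
      d0 <- sqrt((loc[, 1L] - targets[j, 1L])^2 + (loc[, 2L] - targets[j, 2L])^2)
      nb <- which(d0 <= radius)
      if (!length(nb)) { pred[j] <- NA_real_; varr[j] <- NA_real_; next }
      A <- ok_lhs(vg, loc[nb, , drop = FALSE])
      g0 <- c(sv_distinct(vg, d0[nb]), 1)
      sol <- drop(solve(A, g0))
      lam <- sol[seq_along(nb)]
      muj <- sol[length(nb) + 1L]
      taper <- pmin(1, pmax(0, (radius - d0[nb]) / (radius * (1 - smoothing))))
      lt <- lam * taper
      if (abs(sum(lt)) < 1e-12) lt <- taper / sum(taper) else lt <- lt / sum(lt)
      pred[j] <- sum(lt * residuals[nb])
      varr[j] <- sum(lt * g0[seq_along(nb)]) + muj
      mu[j] <- muj
      if (keep_weights) { wts[[j]] <- lt; idx[[j]] <- nb }
    }
  }
  neg <- !is.na(varr) & varr < 0
  if (any(varr[neg] < -1e-8))
    warning("kriging variance < -1e-8 clipped to zero at ",
            sum(varr[neg] < -1e-8), " target(s)")
  varr[neg] <- 0
  list(prediction = pred, variance = varr, mu = mu,
       weights = wts, index = idx)
}

#' Kriged isoscape surface on a regular grid
#'
#' Ordinary kriging of detrended residuals at every cell centre of a
#' regular grid, with the polynomial trend added back to the predictions.
#' Standard errors come from the kriging variance of the residual field
#' (the trend is treated as fixed, as in the producing workflow; trend
#' estimation variance is not propagated).
#'
#' @inheritParams krige_point
#' @param values raw (not detrended) sample values.
#' @param trend a [fit_trend()] surface.
#' @param cell_size square cell side, metres (default 5000).
#' @param bbox optional `c(xmin, xmax, ymin, ymax)`; default the sample
#'   bounding box padded by one cell.
#' @return A `kriging_surface` object: `prediction` and `se` matrices
#'   (rows = northing, increasing with row index; cols = easting), `x`/`y`
#'   cell-centre coordinates, `cell_size`, `origin`.
#' @export
krige_grid <- function(locations, values, trend, vg, cell_size = 5000,
                       bbox = NULL, neighbourhood = "global",
                       radius = NULL, smoothing = 0.5) {
  loc <- stop_if_not_coords(locations)
  stopifnot(inherits(trend, "trend_surface"), inherits(vg, "variogram_model"),
            cell_size > 0)
  if (is.null(bbox))
    bbox <- c(min(loc[, 1L]) - cell_size, max(loc[, 1L]) + cell_size,
              min(loc[, 2L]) - cell_size, max(loc[, 2L]) + cell_size)
  x <- seq(bbox[1L] + cell_size / 2, bbox[2L], by = cell_size)
  y <- seq(bbox[3L] + cell_size / 2, bbox[4L], by = cell_size)
  targets <- as.matrix(expand.grid(easting = x, northing = y))
  res <- detrend(values, trend, loc)
  kr <- krige_points(targets, loc, res, vg, neighbourhood, radius, smoothing)
  pred <- retrend(kr$prediction, trend, targets)
  P <- matrix(pred, nrow = length(y), ncol = length(x), byrow = TRUE)
  S <- matrix(sqrt(kr$variance), nrow = length(y), ncol = length(x), byrow = TRUE)
  structure(list(prediction = P, se = S, x = x, y = y,
                 cell_size = cell_size,
                 origin = c(bbox[1L], bbox[3L]),
                 n_rows = length(y), n_cols = length(x)),
            class = "kriging_surface")
}

#' @export
print.kriging_surface <- function(x, ...) {
  cat(sprintf("Kriged surface: %d x %d cells of %g km\n",
              x$n_rows, x$n_cols, x$cell_size / 1000))
  cat(sprintf("prediction range [%.2f, %.2f], SE range [%.3f, %.3f]\n",
              min(x$prediction, na.rm = TRUE), max(x$prediction, na.rm = TRUE),
              min(x$se, na.rm = TRUE), max(x$se, na.rm = TRUE)))
  invisible(x)
}

#' Write a surface raster as an ESRI ASCII grid
#'
#' @param surface a `kriging_surface`.
#' @param path output file (`.asc`).
#' @param layer `"prediction"` or `"se"`.
#' @param nodata value written for missing cells.
#' @export
write_asc <- function(surface, path, layer = c("prediction", "se"),
                      nodata = -9999) {
  stopifnot(inherits(surface, "kriging_surface"))
  layer <- match.arg(layer)
  M <- surface[[layer]]
  M[!is.finite(M)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", surface$n_cols),
               sprintf("nrows %d", surface$n_rows),
               sprintf("xllcorner %.3f", surface$origin[1L]),
               sprintf("yllcorner %.3f", surface$origin[2L]),
               sprintf("cellsize %.3f", surface$cell_size),
               sprintf("NODATA_value %g", nodata)), con)
  # ESRI grids run north-to-south: write rows top (max northing) first
  utils::write.table(M[rev(seq_len(surface$n_rows)), , drop = FALSE], con,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Leave-one-out cross-validation of the kriging model
#'
#' Each sample is removed in turn and predicted from the rest with the
#' trend and variogram held fixed (matching the producing workflow, in
#' which cross-validation does not refit the model). Errors are
#' `predicted - measured`; standardized errors divide by the per-sample
#' kriging standard error.
#'
#' @inheritParams krige_grid
#' @param ids optional sample identifiers.
#' @return A list of class `kriging_cv`: `records` data frame
#'   (`sample_id`, `measured`, `predicted`, `error`, `se`, `std_error`) and
#'   `summary` list (`n`, `mean_error`, `rms`, `std_mean`, `std_rms`,
#'   `avg_se`).
#' @export
loo_cv <- function(locations, values, trend, vg, neighbourhood = "global",
                   radius = NULL, smoothing = 0.5, ids = NULL) {
  loc <- stop_if_not_coords(locations)
  n <- nrow(loc)
  stopifnot(n >= 3L, length(values) == n)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  res <- detrend(values, trend, loc)
  pred <- se <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    kr <- tryCatch(
      krige_points(loc[i, , drop = FALSE], loc[-i, , drop = FALSE], res[-i],
                   vg, neighbourhood, radius, smoothing),
      error = function(e) NULL)
    if (is.null(kr) || is.na(kr$prediction[1L])) next
    pred[i] <- kr$prediction[1L]
    se[i] <- sqrt(kr$variance[1L])
  }
  pred <- pred + predict_trend(trend, loc)
  err <- pred - values
  std <- err / se
  ok <- is.finite(err) & is.finite(std)
  if (any(!ok))
    warning(sum(!ok), " sample(s) had no usable neighbours and are excluded ",
            "from the cross-validation summary")
  records <- data.frame(sample_id = ids, measured = values, predicted = pred,
                        error = err, se = se, std_error = std,
                        stringsAsFactors = FALSE)
  summary <- list(n = sum(ok),
                  mean_error = mean(err[ok]),
                  rms = sqrt(mean(err[ok]^2)),
                  std_mean = mean(std[ok]),
                  std_rms = sqrt(mean(std[ok]^2)),
                  avg_se = mean(se[ok]))
  structure(list(records = records, summary = summary), class = "kriging_cv")
}

#' @export
print.kriging_cv <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Leave-one-out CV: n = %d; mean = %.3f; RMS = %.3f;\n  standardized mean = %.3f; standardized RMS = %.3f; average SE = %.3f\n",
    s$n, s$mean_error, s$rms, s$std_mean, s$std_rms, s$avg_se))
  invisible(x)
}
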