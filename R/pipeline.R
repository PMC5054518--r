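#' Classify cross-validation residuals into mobility classes
#'
#' Residuals are `predicted - measured` leave-one-out errors. Samples whose
#' residual exceeds `+threshold` are classed `enriched`, below `-threshold`
#' `depleted`, otherwise `local` (strict inequalities). The default 0.6
#' permil corresponds to about twice the typical replicate measurement
#' error of enamel phosphate analyses. A signed bin index
#' `sign(error) * floor(|error| / bin)` supports residual maps incremented
#' in steps of `bin` (default 0.3 permil).
#'
#' @param errors numeric vector of CV errors (predicted - measured).
#' @param threshold positive per-mil threshold, default 0.6.
#' @param bin positive per-mil bin width, default 0.3.
#' @return data frame with `error`, `class` (factor
#'   enriched/depleted/local) and `bin` (signed integer).
#' @export
classify_residuals <- function(errors, threshold = 0.6, bin = 0.3) {
  stopifnot(threshold > 0, bin > 0)
  cl <- rep("local", length(errors))
  cl[errors > threshold] <- "enriched"
  cl[errors < -threshold] <- "depleted"
  cl[!is.finite(errors)] <- NA
  data.frame(error = errors,
             class = factor(cl, levels = c("enriched", "depleted", "local")),
             bin = ifelse(is.finite(errors),
                          sign(errors) * floor(abs(errors) / bin), NA))
}

#' Run the full mobility analysis pipeline
#'
#' End-to-end orchestration of the geostatistical mobility analysis, in a
#' fixed, logged order: geographic exclusion (outside-domain samples) ->
#' summary statistics and normality -> global Moran's I -> local Moran's I
#' with FDR-classified clusters/outliers -> exclusion of HL/LH spatial
#' outliers (cluster cores HH/LL are retained) -> declustered trend and
#' variogram (fitted, or fixed published parameters) -> ordinary-kriging
#' surface -> leave-one-out cross-validation -> residual mobility
#' classification. Fully reproducible for a fixed seed.
#'
#' @param samples an `isotope_samples` data frame.
#' @param threshold neighbour threshold in metres; `NULL` (default) uses
#'   [min_connecting_threshold()] of the retained locations.
#' @param idw_power inverse-distance weight exponent, default 1.
#' @param fdr_alpha FDR level for the LISA classification, default 0.05.
#' @param inference LISA inference mode, `"permutation"` or `"analytic"`.
#' @param n_perm conditional permutations for LISA, default 999.
#' @param seed master seed; per-stage child seeds are derived from it.
#' @param trend_order polynomial trend order, default 2.
#' @param variogram `"fit"` or a fixed [stable_variogram()].
#' @param residual_threshold,residual_bin see [classify_residuals()].
#' @param decluster_cell declustering cell size, metres.
#' @param grid_cell kriging grid cell size in metres; `NULL` skips the
#'   surface (cross-validation still runs).
#' @param neighbourhood kriging neighbourhood mode.
#' @param exclude_offperiod drop samples outside the period window
#'   (default FALSE: they are part of the published dataset).
#' @return A `mobility_report` object.
#' @export
run_mobility <- function(samples, threshold = NULL, idw_power = 1,
                         fdr_alpha = 0.05,
                         inference = c("permutation", "analytic"),
                         n_perm = 999, seed = 1, trend_order = 2,
                         variogram = "fit", residual_threshold = 0.6,
                         residual_bin = 0.3, decluster_cell = 50000,
                         grid_cell = NULL,
                         neighbourhood = c("global", "smoothed"),
                         exclude_offperiod = FALSE) {
  stopifnot(is.data.frame(samples))
  inference <- match.arg(inference)
  neighbourhood <- match.arg(neighbourhood)
  n_input <- nrow(samples)
  if (!n_input) stop("empty sample table")

  # stage 1: geographic / period exclusions
  keep <- samples$in_britain
  if (exclude_offperiod) keep <- keep & samples$period_ok
  geo <- samples[keep, , drop = FALSE]
  n_geo <- nrow(geo)
  if (n_geo < 10L) stop("fewer than 10 samples retained after exclusions")
  loc <- as.matrix(geo[, c("easting", "northing")])

  # stage 2: distributional summaries (all three candidate subsets)
  summaries <- list(all = isotope_summary(samples$d18Op),
                    britain = isotope_summary(geo$d18Op))

  # stage 3: global + local spatial autocorrelation
  thr <- if (is.null(threshold)) min_connecting_threshold(loc) else threshold
  W <- build_weights(loc, threshold = thr, idw_power = idw_power,
                     row_standardize = TRUE)
  moran <- moran_test(geo$d18Op, W)
  lisa <- local_moran(geo$d18Op, W, inference = inference, n_perm = n_perm,
                      seed = child_seed(seed, "lisa"), alpha = fdr_alpha)
  lisa <- cbind(sample_id = geo$sample_id, lisa)

  # stage 4: exclude spatial outliers (HL/LH) from the model
  outlier <- lisa$cluster %in% c("HL", "LH")
  retained <- geo[!outlier, , drop = FALSE]
  n_retained <- nrow(retained)
  summaries$retained <- isotope_summary(retained$d18Op)

  # stage 5: the geostatistical model (declustered trend + variogram + OK)
  fit <- isoscape(retained, variogram = variogram, trend_order = trend_order,
                  decluster_cell = decluster_cell,
                  neighbourhood = neighbourhood)
  surface <- if (!is.null(grid_cell)) predict(fit, cell_size = grid_cell) else NULL

  # stage 6: cross-validation + residual mobility classes
  cvr <- cv(fit)
  classes <- classify_residuals(cvr$records$error,
                                threshold = residual_threshold,
                                bin = residual_bin)
  per_sample <- data.frame(
    sample_id = retained$sample_id,
    easting = retained$easting, northing = retained$northing,
    d18Op = retained$d18Op,
    lisa_class = lisa$cluster[!outlier],
    cv_error = cvr$records$error, cv_se = cvr$records$se,
    residual_class = classes$class, residual_bin = classes$bin,
    stringsAsFactors = FALSE)

  counts <- c(input = n_input, after_geography = n_geo,
              spatial_outliers = sum(outlier), retained = n_retained)
  stopifnot(counts[["after_geography"]] ==
              counts[["spatial_outliers"]] + counts[["retained"]])

  config <- list(threshold = thr, idw_power = idw_power,
                 fdr_alpha = fdr_alpha, inference = inference,
                 n_perm = n_perm, seed = seed, trend_order = trend_order,
                 variogram = if (identical(variogram, "fit")) "fit"
                             else unclass(variogram),
                 residual_threshold = residual_threshold,
                 residual_bin = residual_bin,
                 decluster_cell = decluster_cell, grid_cell = grid_cell,
                 neighbourhood = neighbourhood,
                 exclude_offperiod = exclude_offperiod)
  structure(list(per_sample = per_sample, lisa = lisa, moran = moran,
                 summaries = summaries, fit = fit, surface = surface,
                 cv = cvr, counts = counts,
                 outlier_ids = geo$sample_id[outlier],
                 config = config),
            class = "mobility_report")
}

#' @export
print.mobility_report <- function(x, ...) {
  cat("Mobility analysis report\n========================\n")
  cat(sprintf("samples: %d input, %d after geography, %d spatial outliers excluded, %d retained\n",
              x$counts[["input"]], x$counts[["after_geography"]],
              x$counts[["spatial_outliers"]], x$counts[["retained"]]))
  if (length(x$outlier_ids))
    cat("spatial outliers:", paste(x$outlier_ids, collapse = ", "), "\n")
  print(x$moran)
  print(x$cv)
  tab <- table(x$per_sample$residual_class)
  cat("residual classes:",
      paste(names(tab), as.integer(tab), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# short deterministic polynomial hash of the configuration
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write a mobility report to disk
#'
#' Emits a machine-readable JSON summary, per-sample / LISA / CV tables as
#' CSV, prediction and standard-error rasters as ESRI ASCII grids (when a
#' surface was kriged), and a GeoJSON of classified points (planar
#' EPSG:27700 coordinates). Outputs are deterministic: re-running with the
#' same configuration and seed reproduces them byte for byte.
#'
#' @param report a [run_mobility()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "mobility_report"))
  if (report$counts[["retained"]] == 0L) stop("no retained samples; nothing to write")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(summary = file.path(dir, "summary.json"),
             per_sample = file.path(dir, "samples.csv"),
             lisa = file.path(dir, "lisa.csv"),
             cv = file.path(dir, "cv.csv"),
             points = file.path(dir, "points.geojson"))
  s <- report$cv$summary
  jsonlite::write_json(list(
    config = report$config, config_hash = config_hash(report$config),
    counts = as.list(report$counts),
    outlier_ids = report$outlier_ids,
    moran = unclass(report$moran),
    summaries = lapply(report$summaries, function(x) unclass(x)),
    cv_summary = list(n = s$n, mean_error = s$mean_error, rms = s$rms,
                      std_mean = s$std_mean, std_rms = s$std_rms,
                      avg_se = s$avg_se),
    residual_classes = as.list(table(report$per_sample$residual_class))),
    paths[["summary"]], auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.csv(report$per_sample, paths[["per_sample"]], row.names = FALSE)
  utils::write.csv(report$lisa, paths[["lisa"]], row.names = FALSE)
  utils::write.csv(report$cv$records, paths[["cv"]], row.names = FALSE)
  features <- lapply(seq_len(nrow(report$per_sample)), function(i) {
    r <- report$per_sample[i, ]
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(r$easting, r$northing)),
         properties = list(sample_id = r$sample_id, d18Op = r$d18Op,
                           lisa_class = as.character(r$lisa_class),
                           residual_class = as.character(r$residual_class),
                           cv_error = r$cv_error))
  })
  jsonlite::write_json(list(type = "FeatureCollection",
                            crs = list(type = "name",
                                       properties = list(name = "EPSG:27700")),
                            features = features),
                       paths[["points"]], auto_unbox = TRUE, digits = NA)
  if (!is.null(report$surface)) {
    paths <- c(paths, prediction = file.path(dir, "prediction.asc"),
               se = file.path(dir, "se.asc"))
    write_asc(report$surface, paths[["prediction"]], "prediction")
    write_asc(report$surface, paths[["se"]], "se")
  }
  invisible(paths)
}
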