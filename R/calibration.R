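#' Two-point linear calibration of isotope measurements
#'
#' Laboratories correct raw delta values against two bracketing silver
#' phosphate working standards with known (assigned) compositions, e.g.
#' TU1 = 21.1 permil and TU2 = 5.5 permil. `calibration_pair()` bundles one
#' standard's assigned value with its in-run measured value;
#' `calibrate_two_point()` applies the unique affine map sending the two
#' measured values to the two assigned values.
#'
#' @param assigned reference (true) value of the standard, permil.
#' @param measured observed in-run value of the standard, permil.
#' @return `calibration_pair()`: a `calibration_pair` object.
#' @export
calibration_pair <- function(assigned, measured) {
  stopifnot(is.numeric(assigned), is.numeric(measured),
            length(assigned) == 1L, length(measured) == 1L,
            is.finite(assigned), is.finite(measured))
  structure(list(assigned = assigned, measured = measured),
            class = "calibration_pair")
}

#' @rdname calibration_pair
#' @param raw numeric vector of raw measured values, permil.
#' @param low,high `calibration_pair` objects for the low and high standard;
#'   the two assigned values (and the two measured values) must differ.
#' @return `calibrate_two_point()`: corrected values, permil.
#' @examples
#' low  <- calibration_pair(assigned = 5.5,  measured = 5.0)
#' high <- calibration_pair(assigned = 21.1, measured = 20.0)
#' calibrate_two_point(12.5, low, high)  # 13.3
#' @export
calibrate_two_point <- function(raw, low, high) {
  stopifnot(inherits(low, "calibration_pair"), inherits(high, "calibration_pair"),
            is.numeric(raw))
  if (high$assigned == low$assigned)
    stop("degenerate calibration: identical assigned values")
  if (high$measured == low$measured)
    stop("degenerate calibration: identical measured values")
  slope <- (high$assigned - low$assigned) / (high$measured - low$measured)
  low$assigned + slope * (raw - low$measured)
}

#' Delta notation for isotope ratios
#'
#' delta = (R_sample / R_standard - 1) x 1000, in permil.
#'
#' @param r_sample,r_standard isotopic ratios (dimensionless);
#'   `r_standard` must be positive.
#' @return per-mil delta values.
#' @export
delta_from_ratio <- function(r_sample, r_standard) {
  stopifnot(is.numeric(r_sample), is.numeric(r_standard))
  if (any(r_standard <= 0)) stop("r_standard must be positive")
  (r_sample / r_standard - 1) * 1000
}
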