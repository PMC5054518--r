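#' Parse British National Grid references
#'
#' Converts 4-figure Ordnance Survey grid references (two letters + four
#' digits, e.g. `"TQ3080"`) to planar OSGB36 / EPSG:27700 coordinates in
#' metres. A 4-figure reference identifies a 1 km square; the coordinates
#' returned are the *centre* of that square (south-west corner + 500 m on
#' each axis), the natural point estimate for data located "to the nearest
#' 1 km square". Users whose conventions differ (e.g. SW corner) should
#' supply explicit easting/northing instead.
#'
#' The letter pair is decoded with the standard OSGB lettering scheme: each
#' letter indexes a 5 x 5 block of squares (500 km for the first letter,
#' 100 km for the second), read west-to-east and north-to-south, with the
#' letter I unused.
#'
#' @param gridref character vector of 4-figure grid references
#'   (case-insensitive; internal whitespace allowed).
#' @return A two-column numeric matrix with columns `easting` and
#'   `northing` (metres), one row per reference.
#' @examples
#' parse_ngr("SV0000")   # (500, 500): SV is the false-origin 100 km square
#' parse_ngr("TQ3080")   # (530500, 180500)
#' @export
parse_ngr <- function(gridref) {
  stopifnot(is.character(gridref))
  g <- toupper(gsub("[[:space:]]", "", gridref))
  ok <- grepl("^[A-HJ-Z]{2}[0-9]{4}$", g)
  if (any(!ok))
    stop("malformed grid reference(s): ",
         paste(unique(gridref[!ok]), collapse = ", "),
         " (expected two OSGB letters, I excluded, followed by 4 digits)")
  letters25 <- strsplit("ABCDEFGHJKLMNOPQRSTUVWXYZ", "")[[1]]
  idx <- function(ch) match(ch, letters25) - 1L
  l1 <- idx(substr(g, 1L, 1L))
  l2 <- idx(substr(g, 2L, 2L))
  # first letter: 500 km squares, origin offset so that square 'S' starts at (0, 0)
  e <- ((l1 %% 5L) - 2L) * 500000 + (l2 %% 5L) * 100000
  n <- (3L - l1 %/% 5L) * 500000 + (4L - l2 %/% 5L) * 100000
  e <- e + as.numeric(substr(g, 3L, 4L)) * 1000 + 500
  n <- n + as.numeric(substr(g, 5L, 6L)) * 1000 + 500
  if (any(e < 0 | n < 0))
    stop("grid reference(s) fall outside the OSGB grid (negative coordinates): ",
         paste(unique(gridref[e < 0 | n < 0]), collapse = ", "))
  cbind(easting = e, northing = n)
}
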