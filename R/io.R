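#' Read and write isotope sample tables
#'
#' Reads a delimited table of tooth-enamel phosphate oxygen isotope samples
#' (one row per individual) into a validated `isotope_samples` data frame.
#' Column names are resolved through a `dialect` mapping so tables with
#' different headers can be ingested without editing the file. Coordinates
#' are taken from explicit easting/northing columns when present, otherwise
#' parsed from a 4-figure grid reference with [parse_ngr()]. Rows whose
#' isotope value is missing are dropped with a warning naming each dropped
#' row; a row with neither coordinates nor a grid reference is an error.
#'
#' The returned data frame always carries the columns `sample_id`,
#' `site_name`, `region_code`, `ngr`, `easting`, `northing`, `d18Op`, `sd`,
#' `n_replicates`, `period_ok` and `in_britain`. `in_britain` is derived
#' from the region code (17 = Republic of Ireland is outside the modelling
#' domain) unless supplied explicitly.
#'
#' @param path file to read (CSV by default; TSV if the name ends in
#'   `.tsv`/`.txt` or `sep` is given).
#' @param dialect named character vector mapping canonical names (names of
#'   the vector) to the column names used in the file. Only names present
#'   in the file are used; `sample_id` and `d18Op` plus a location source
#'   are required.
#' @param sep field separator; guessed from the file extension when `NULL`.
#' @return An `isotope_samples` data frame.
#' @seealso [write_samples()], [isotope_summary()]
#' @export
read_samples <- function(path, dialect = default_dialect(), sep = NULL) {
  if (!file.exists(path)) stop("cannot read sample table: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", comment.char = "")
  as_isotope_samples(raw, dialect = dialect)
}

#' @rdname read_samples
#' @export
default_dialect <- function() {
  c(sample_id = "sample_id", site_name = "site_name",
    region_code = "region_code", ngr = "ngr",
    easting = "easting", northing = "northing",
    d18Op = "d18Op", sd = "sd", n_replicates = "n_replicates",
    period_ok = "period_ok", in_britain = "in_britain")
}

#' @rdname read_samples
#' @param x a data frame of raw (character or typed) columns.
#' @export
as_isotope_samples <- function(x, dialect = default_dialect()) {
  stopifnot(is.data.frame(x))
  get_col <- function(canon) {
    # unmapped canonical fields fall back to their canonical column name
    col <- if (canon %in% names(dialect)) dialect[[canon]] else canon
    if (col %in% names(x)) x[[col]] else NULL
  }
  id <- get_col("sample_id")
  if (is.null(id)) stop("no sample id column resolvable via the dialect")
  id <- as.character(id)
  n <- length(id)

  d18_raw <- get_col("d18Op")
  if (is.null(d18_raw)) stop("no d18Op column resolvable via the dialect")
  d18_chr <- trimws(as.character(d18_raw))
  d18 <- suppressWarnings(as.numeric(d18_chr))
  bad_text <- !is.na(d18_chr) & d18_chr != "" & d18_chr != "NA" & is.na(d18)
  if (any(bad_text))
    stop("non-numeric isotope value(s) for sample(s): ",
         paste(id[bad_text], collapse = ", "))

  num_col <- function(canon) {
    v <- get_col(canon)
    if (is.null(v)) return(rep(NA_real_, n))
    suppressWarnings(as.numeric(as.character(v)))
  }
  chr_col <- function(canon) {
    v <- get_col(canon)
    if (is.null(v)) return(rep(NA_character_, n))
    out <- trimws(as.character(v))
    out[out == ""] <- NA_character_
    out
  }
  lgl_col <- function(canon, default) {
    v <- get_col(canon)
    if (is.null(v)) return(rep(default, n))
    out <- as.logical(as.character(v))
    out[is.na(out)] <- default
    out
  }

  site <- chr_col("site_name")
  region <- suppressWarnings(as.integer(num_col("region_code")))
  ngr <- chr_col("ngr")
  easting <- num_col("easting")
  northing <- num_col("northing")
  sdv <- num_col("sd")
  nrep <- suppressWarnings(as.integer(num_col("n_replicates")))
  period_ok <- lgl_col("period_ok", TRUE)

  # fill coordinates from grid references where absent
  need <- is.na(easting) | is.na(northing)
  has_ngr <- !is.na(ngr)
  if (any(need & has_ngr)) {
    en <- parse_ngr(ngr[need & has_ngr])
    easting[need & has_ngr] <- en[, "easting"]
    northing[need & has_ngr] <- en[, "northing"]
  }
  keep_val <- !is.na(d18)
  no_loc <- keep_val & (is.na(easting) | is.na(northing))
  if (any(no_loc))
    stop("sample(s) with neither grid reference nor coordinates: ",
         paste(id[no_loc], collapse = ", "))
  if (any(!keep_val))
    warning("dropping ", sum(!keep_val), " row(s) with missing d18Op: ",
            paste(id[!keep_val], collapse = ", "))

  in_brit_col <- get_col("in_britain")
  in_britain <- if (!is.null(in_brit_col)) {
    v <- as.logical(as.character(in_brit_col)); v[is.na(v)] <- TRUE; v
  } else {
    is.na(region) | region != 17L
  }

  out <- data.frame(sample_id = id, site_name = site, region_code = region,
                    ngr = ngr, easting = easting, northing = northing,
                    d18Op = d18, sd = sdv, n_replicates = nrep,
                    period_ok = period_ok, in_britain = in_britain,
                    stringsAsFactors = FALSE)
  out <- out[keep_val, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("isotope_samples", "data.frame")
  out
}

#' @rdname read_samples
#' @param samples an `isotope_samples` data frame.
#' @export
write_samples <- function(samples, path) {
  stopifnot(is.data.frame(samples))
  utils::write.csv(as.data.frame(samples), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Summary statistics with a normality check
#'
#' Mean, SD, range and the Shapiro-Wilk normality test for a vector of
#' per-mil isotope values. The normality fields are `NA` (with
#' `shapiro_ok = FALSE`) when fewer than 3 finite values are supplied.
#'
#' @param values numeric vector, permil.
#' @return A list of class `isotope_summary` with fields `n`, `mean`, `sd`,
#'   `min`, `max`, `shapiro_W`, `shapiro_p`, `shapiro_ok`.
#' @export
isotope_summary <- function(values) {
  v <- values[is.finite(values)]
  n <- length(v)
  if (n == 0L) stop("no finite values")
  out <- list(n = n, mean = mean(v), sd = stats::sd(v),
              min = min(v), max = max(v),
              shapiro_W = NA_real_, shapiro_p = NA_real_, shapiro_ok = FALSE)
  if (n >= 3L && n <= 5000L && stats::sd(v) > 0) {
    sw <- stats::shapiro.test(v)
    out$shapiro_W <- unname(sw$statistic)
    out$shapiro_p <- sw$p.value
    out$shapiro_ok <- TRUE
  }
  class(out) <- "isotope_summary"
  out
}

#' @export
print.isotope_summary <- function(x, digits = 3, ...) {
  cat(sprintf("n = %d, mean = %.*f, sd = %.*f, range = [%.*f, %.*f]\n",
              x$n, digits, x$mean, digits, x$sd, digits, x$min, digits, x$max))
  if (x$shapiro_ok)
    cat(sprintf("Shapiro-Wilk: W = %.3f, p = %.3f\n", x$shapiro_W, x$shapiro_p))
  else cat("Shapiro-Wilk: not computed\n")
  invisible(x)
}
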