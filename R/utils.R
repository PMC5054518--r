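# internal helpers shared across the package

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  code
}

# Derive a reproducible child seed from a master seed; keeps results < 2^31.
child_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  offs <- sum(utf8ToInt(stage)) * 7919L
  as.integer((as.numeric(seed) * 69091 + offs) %% 2147483647)
}

# Pairwise Euclidean distance matrix for a 2-column coordinate matrix.
dist_matrix <- function(loc) {
  loc <- as.matrix(loc)
  as.matrix(stats::dist(loc))
}

stop_if_not_coords <- function(loc) {
  loc <- as.matrix(loc)
  if (ncol(loc) != 2L || !is.numeric(loc) || anyNA(loc) || any(!is.finite(loc)))
    stop("locations must be a numeric matrix with two finite columns (easting, northing)")
  loc
}
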