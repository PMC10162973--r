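#' @keywords internal
#' @useDynLib invcnn, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed < 0)
    stop("`seed` must be a single non-negative number", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and an index, staying below 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 1000003 + as.double(index) * 7919) %% 2147483647)
}

stopifnot_scalar <- function(x, name, lower = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower)
    stop(sprintf("`%s` must be a single number >= %s", name, lower), call. = FALSE)
  invisible(x)
}
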