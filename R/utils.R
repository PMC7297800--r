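#' @useDynLib periprog, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif fft median sd predict coef pt rbinom
#' @importFrom utils write.csv read.csv
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-subject / per-repeat seed derived from a base seed,
# kept inside the 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483629)
}

as_mask <- function(x, arg = deparse(substitute(x))) {
  if (is.logical(x)) return(x)
  if (is.numeric(x) && all(x %in% c(0, 1)))
    return(array(x != 0, dim = dim(x)))
  stop(sprintf("'%s' must be a binary (logical or 0/1) mask", arg))
}

check_same_dim <- function(...) {
  dims <- lapply(list(...), dim)
  ref <- dims[[1]]
  for (d in dims)
    if (!identical(d, ref)) stop("masks/volumes must share the same grid dimensions")
  invisible(ref)
}
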