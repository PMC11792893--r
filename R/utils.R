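#' @useDynLib amphistom, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median cor lm coef p.adjust pf quantile rgamma rnorm
#'   runif rpois complete.cases
#' @importFrom utils read.csv write.csv
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. seed = NULL means "use the current
# stream" (and advance it).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Derive a child seed from a master seed and a task index, keeping the result
# inside the 32-bit integer range. Documented scheme: child = (seed * 48271 +
# index) mod (2^31 - 1), the Lehmer multiplier, so partial re-runs of the
# pipeline reproduce per-task streams.
derive_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + index) %% 2147483647)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
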