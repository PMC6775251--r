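#' @keywords internal
"_PACKAGE"

#' @useDynLib pyrexc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx cor runif rexp setNames
#' @importFrom utils read.csv write.csv modifyList
NULL

stop_pyrexc <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a locally seeded RNG, restoring the global RNG state after.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-stage seed expansion from one top-level seed. Kept below
# 2^31 so it is always a valid R integer.
derive_seed <- function(seed, ...) {
  if (is.null(seed)) return(NULL)
  x <- as.double(seed) %% 2147483629
  for (k in c(...)) {
    kk <- if (is.character(k)) sum(utf8ToInt(k) * seq_along(utf8ToInt(k))) else as.double(k)
    x <- (x * 48271 + kk) %% 2147483629
  }
  as.integer(x) + 1L
}

# trapezoid quadrature on an (x, y) grid
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}
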