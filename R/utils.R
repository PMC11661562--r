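#' @useDynLib survforestbench, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rexp rbinom qnorm qgamma qexp pnorm pchisq
#'   uniroot rmultinom var sd cor
#' @importFrom utils write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a local RNG state seeded with `seed`; the caller's RNG
# state is restored afterwards. seed = NULL uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Deterministic substream derivation: keeps derived seeds in 32-bit range.
derive_seed <- function(seed, ...) {
  parts <- c(...)
  s <- as.double(seed) %% 2147483629
  for (p in parts) s <- (s * 48271 + as.double(p) * 9973 + 1) %% 2147483629
  as.integer(s)
}

stop_named <- function(class, msg, ...) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}
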