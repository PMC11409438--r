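#' @keywords internal
"_PACKAGE"

#' @useDynLib wormscreen, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm rpois rbinom median lm coef sd residuals
#' @importFrom utils read.csv write.csv packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

MOD31 <- 2147483647

# polynomial string hash on a 31-bit field; used only to derive RNG substreams
hash_string <- function(s) {
  if (is.na(s) || !nzchar(s)) return(0)
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% MOD31
  h
}

#' Derive a reproducible sub-seed from a top-level seed and identifiers
#'
#' All stochastic stages draw from substreams keyed by plate/well identity, so
#' adding or removing wells never perturbs the draws of other wells.
#'
#' @param seed integer top-level seed.
#' @param ... identifiers (coerced to character) mixed into the stream key.
#' @return an integer seed in [1, 2^31-2].
#' @export
derive_seed <- function(seed, ...) {
  h <- as.numeric(seed) %% MOD31
  for (part in list(...)) {
    h <- (h * 48271 + hash_string(as.character(part)) + 1) %% MOD31
  }
  as.integer(h %% (MOD31 - 2) + 1)
}

# evaluate code under a local RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_ws <- function(...) stop(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x == round(x)
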