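# Internal helpers shared across modules.

#' Derive a reproducible child seed from a run seed
#'
#' Every stochastic stage of the pipeline draws its RNG stream from the run
#' seed through this function, so that re-running a single stage from cached
#' inputs reproduces its output exactly. The map is a Lehmer-style congruence
#' kept strictly below 2^31 so the result is always a valid R integer seed.
#'
#' @param seed integer run seed.
#' @param offset integer stream offset (one per stage / chain / replicate).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(offset), length(offset) == 1L, is.finite(offset))
  as.integer((abs(as.numeric(seed)) * 48271 + abs(as.numeric(offset)) * 69621) %% 2147483587)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_stage <- function(stage, msg, call. = FALSE) {
  stop(sprintf("[%s] %s", stage, msg), call. = call.)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == floor(x)
}
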