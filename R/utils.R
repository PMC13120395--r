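# Internal helpers shared across modules.

#' Derive a child RNG seed from a root seed and an index path
#'
#' Every stochastic stage of the package draws its seed from one root seed
#' through this function, so that multi-stage generation (cohort -> slide ->
#' tile) is reproducible while stages remain independently re-runnable.
#' The scheme is a multiplicative congruential mix modulo the Mersenne prime
#' 2^31 - 1; all intermediates stay below 2^53 so double arithmetic is exact.
#'
#' @param seed integer root seed (non-negative, below 2^31).
#' @param ... integer indices identifying the stream (e.g. cat index, slide
#'   index, tile index).
#' @return a single integer in [1, 2^31 - 2] usable with [set.seed()].
#' @export
split_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1
  s <- as.double(seed) %% m
  for (k in c(...)) {
    s <- (s * 48271 + (as.double(k) + 1) * 16807) %% m
  }
  as.integer(s %% (m - 2) + 1)
}

# stop() with a classed condition so callers can test for error families
stop_oralcyto <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "oralcyto_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

# linear-interpolation quantiles (type 7) used everywhere in the package
.quartiles <- function(x) {
  stats::quantile(x, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 1 && x == round(x)
}
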