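#' Derive a reproducible child seed from a root seed and a label path
#'
#' A single root seed drives the whole simulator; independent random streams
#' for sub-experiments (per compartment, replicate, isotope, ...) are derived
#' deterministically so any subset of the design can be regenerated on its own.
#' The hash is a 31-based polynomial over the label string, reduced modulo
#' 2^31 - 1 so the result is always a valid 32-bit R integer.
#'
#' @param seed integer root seed.
#' @param ... label components (coerced to character) identifying the stream.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @examples
#' derive_seed(1, "gradient", "rhizosphere", 2, "13C")
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  label <- paste(c(format(seed), vapply(list(...), format, "")), collapse = "/")
  h <- 0
  for (cp in utf8ToInt(label)) h <- (h * 31 + cp) %% 2147483647
  as.integer(h)
}

# run `expr`-style code under a derived seed without disturbing the caller's
# RNG state beyond what set.seed() implies (simulator functions document that
# they reset the stream from their `seed` argument).
with_seed_ <- function(seed, fun) {
  if (!is.null(seed)) set.seed(seed)
  fun()
}
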