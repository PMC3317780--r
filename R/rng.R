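#' Derive a named RNG substream seed from a master seed
#'
#' One top-level seed fans out to named substreams (noise, seeding, sampling,
#' ...) so that independent pipeline stages draw from decoupled streams while
#' the whole run stays reproducible from a single integer.  The derived seed
#' is always a positive integer below 2^31.
#'
#' @param seed master seed (integer).
#' @param name substream name (character scalar).
#' @param index optional non-negative integer offset within the substream
#'   (e.g. one seed per streamline attempt).
#' @return an integer seed suitable for [set.seed()].
#' @export
substream_seed <- function(seed, name, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 1000003
  val <- ((abs(seed) %% 2147483647) * 48271) %% 2147483647
  val <- (val + h * 97003 + index * 7919 + 1) %% 2147483629
  as.integer(val + 1)
}
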