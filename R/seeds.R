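#' Derive a named substream seed from a master seed
#'
#' All stochastic stages (covariate synthesis, outcome noise, bootstrap
#' expansion, residual draws, per-replicate streams) draw their seeds from one
#' master seed through this function, so any stage can be re-run in isolation
#' and reproduce its output bit-identically.
#'
#' @param seed master seed (single number).
#' @param stream stream label: a character tag (e.g. `"covariates"`) or an
#'   integer index (e.g. a replicate number).
#' @return An integer seed in `[1, 2^31 - 20)`, suitable for [set.seed()].
#' @export
#' @examples
#' seed_substream(1, "covariates")
#' seed_substream(1, 7L)
seed_substream <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  key <- if (is.character(stream)) {
    sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  } else {
    as.double(stream)
  }
  stopifnot(length(key) == 1L, is.finite(key))
  # multiplicative congruential step (Park-Miller multiplier), kept < 2^31
  val <- (abs(seed) * 48271 + abs(key) * 8191 + 1) %% 2147483629
  as.integer(val + 1)
}

# run code under a substream seed without disturbing the caller's RNG state
with_substream <- function(seed, stream, code) {
  withr::with_seed(seed_substream(seed, stream), code)
}
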