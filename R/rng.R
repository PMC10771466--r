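# Deterministic RNG substreams: one base seed, one named substream per
# simulation stage, so that adding or re-running one stage never perturbs
# the draws of another.

.substream_offsets <- c(
  genotypes   = 101L,
  profiles    = 211L,
  missingness = 307L,
  metadata    = 401L,
  permutation = 503L,
  mixture     = 601L,
  qc          = 701L
)

#' Derive a substream seed from a base seed and a stage name
#'
#' The derivation is a fixed affine map modulo 2^31 - 1, exact in double
#' precision, so the result is a valid 32-bit seed for any base seed below
#' 2^31.
#'
#' @param seed integer base seed.
#' @param stage one of `names(.substream_offsets)`, or an arbitrary string
#'   (hashed by character codes) for ad-hoc streams.
#' @return an integer seed.
#' @keywords internal
substream_seed <- function(seed, stage) {
  off <- if (stage %in% names(.substream_offsets)) {
    as.double(.substream_offsets[[stage]])
  } else {
    sum(utf8ToInt(stage)) %% 104729
  }
  as.integer((as.double(seed) * 7919 + off * 65537) %% 2147483647)
}

# Evaluate `code` under a seeded RNG without disturbing the caller's stream.
with_substream <- function(seed, stage, code) {
  withr::with_seed(substream_seed(seed, stage), code)
}
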