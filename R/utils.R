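#' Derive a deterministic RNG substream seed
#'
#' Folds a master seed and one or more stream indices into a single integer
#' seed via a Lehmer-style congruence, so independent analysis stages (per
#' participant, per SOA, ...) get reproducible, distinct seeds from one
#' master seed. All arithmetic stays below 2^53 and the result is in
#' `[1, 2^31 - 2]`.
#'
#' @param master master seed (integer-valued).
#' @param ... integer stream indices.
#' @return A single integer seed.
#' @export
substream_seed <- function(master, ...) {
  m <- 2147483647 # 2^31 - 1 (prime)
  s <- as.numeric(master) %% m
  for (k in c(...)) {
    s <- (s * 48271 + as.numeric(k) + 1) %% m
  }
  as.integer(s %% (m - 1) + 1)
}
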