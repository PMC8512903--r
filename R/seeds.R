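#' Derive per-component seeds from one top-level seed
#'
#' Every source of randomness in the package is seeded, and pipelines fan a
#' single run seed out to their stages through this deterministic splitter so
#' that adding a stage does not perturb the draws of earlier stages. The
#' stream is a Lehmer multiplicative congruential generator
#' (`s <- 48271 * s mod (2^31 - 1)`), whose products stay exactly
#' representable in doubles.
#'
#' @param seed Integer top-level seed.
#' @param n Number of derived seeds to return.
#' @return Integer vector of `n` seeds in `[1, 2^31 - 2]`.
#' @export
split_seed <- function(seed, n = 1L) {
  m <- 2147483647
  s <- (abs(as.numeric(seed)) %% (m - 1)) + 1
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- (48271 * s) %% m
    out[i] <- s
  }
  as.integer(out)
}
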