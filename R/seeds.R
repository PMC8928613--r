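# Deterministic child-seed derivation so that one master seed spawns
# independent streams per (replicate, purpose) without consuming a shared
# RNG state in an order-dependent way. Counter-based LCG fold; all
# arithmetic stays below 2^53 so doubles are exact, result < 2^31.
derive_seed <- function(seed, ...) {
  counters <- c(...)
  s <- as.numeric(seed) %% 2147483647
  for (cnt in counters) {
    s <- (s * 69069 + as.numeric(cnt) + 1) %% 2147483647
  }
  as.integer(s)
}
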