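# Deterministic fan-out of one run seed into per-stage child seeds, so each
# stage can be re-run in isolation. Kept below 2^31 - 1 (R integers).
child_seed <- function(seed, k) {
  as.integer((as.double(seed) %% 1e6 * 69069 + 12345 + 1000003 * k) %% 2147483629)
}
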