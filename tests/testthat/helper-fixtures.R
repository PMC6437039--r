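# Synthetic n-bit encoding with distinct single-letter abbreviations,
# used to exercise encoding/compiler properties beyond the reference
# 3-bit antibiotic scheme.
synthetic_encoding <- function(n) {
  stopifnot(n >= 1, n <= 13)
  bit_encoding(lapply(seq_len(n), function(i) {
    list(zero = drug(paste0("zero-drug-", i), LETTERS[2 * i - 1]),
         one  = drug(paste0("one-drug-", i),  LETTERS[2 * i]))
  }))
}

# A single well as a minimal plate, for endpoint-equivalence checks.
single_well_plate <- function(on_set, enc, label = "w") {
  plate_design(enc, list(well_spec(1, 1, label, on_set, enc)), c(1, 1),
               device_name = "test well")
}

# Analytic logistic solution for one surviving strain (independent oracle).
logistic_closed_form <- function(t, mu, K, B0) {
  K * B0 * exp(mu * t) / (K + B0 * (exp(mu * t) - 1))
}
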