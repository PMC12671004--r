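# Shared test helpers.

# Uniform phases strictly inside [-pi, pi).
runif_phase <- function(n) runif(n, -pi, pi * (1 - 1e-12))

# PMI with the empty-cell warning silenced (many tests hit sparse joints on
# purpose).
quiet_pmi <- function(...) {
  suppressWarnings(partial_modulation_index(...))
}

# Direct (slow, independent) MI implementation used as an oracle.
oracle_mi <- function(amplitude, bins, n_bins) {
  means <- vapply(seq_len(n_bins), function(b) {
    if (any(bins == b)) mean(amplitude[bins == b]) else 0
  }, numeric(1))
  p <- means / sum(means)
  kl <- sum(ifelse(p > 0, p * log(p / (1 / n_bins)), 0))
  kl / log(n_bins)
}
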