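# Internal helpers shared across modules.

# Round half away from zero (base round() rounds half to even, which would
# make split sizes depend on the parity of n in surprising ways).
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Deterministic 31-bit seed derivation: fold the master seed and the run
# coordinates (stage, algorithm index, configuration index, experiment index)
# through a multiplicative mix so every training run has its own
# reproducible seed. Result always in [1, 2^31 - 2].
derive_seed <- function(master, ...) {
  parts <- c(master, ...)
  h <- 0
  m <- 2147483647  # 2^31 - 1, prime
  for (v in parts) {
    h <- (h * 48271 + (as.numeric(v) %% m) + 11) %% m
  }
  as.integer(h %% (m - 1) + 1)
}

# Full-precision numeric formatting so that text round-trips are
# bit-identical for doubles.
format_full <- function(x) {
  ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
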