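# Small study configurations for fast module-level tests.

small_study_config <- function(seed = 7, ...) {
  study_config(n_genes = 120, n_motifs = 6, n_up = 15, n_down = 15,
               promoter_length_short = 120, promoter_length_long = 400,
               actin_fraction = 0.3, seed = seed, ...)
}

# Consensus-only PWM (deterministic sites; threshold 1 keeps exact
# matches only).
hard_pwm <- function(consensus, id = consensus) {
  consensus_pwm(consensus, id = id, dominance = 1, pseudocount = 0.25)
}
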