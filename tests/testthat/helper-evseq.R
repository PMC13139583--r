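# shared fixture builders (all generated in code; nothing on disk)

# a small deterministic trial with well-separated cues
fixture_trial <- function() {
  trial(left_cues = c(30, 110), right_cues = c(50, 90, 150, 170),
        trial_id = 1L)
}

# trials whose cues are far from the 20 cm gate boundaries and from each
# other, so per-cue effects are clean
fixture_spaced_trials <- function(n, seed = 42) {
  set.seed(seed)
  slots <- seq(10, 190, by = 20) # gate midpoints within the cue region
  lapply(seq_len(n), function(i) {
    k <- sample(3:8, 1)
    pos <- sort(sample(slots, k))
    side <- stats::runif(k) < 0.5
    trial(left_cues = pos[side], right_cues = pos[!side], trial_id = i)
  })
}

# minimal evseq_sim stand-in for readout tests
fake_chain_result <- function(final_L, final_R, n = 17) {
  rates <- matrix(0, 2 * n, 3)
  rates[n, 3] <- final_L
  rates[2 * n, 3] <- final_R
  structure(list(rates = rates, grid = c(-30, 0, 300),
                 params = chain_params(n_positions = n),
                 model = "chain_mutual"),
            class = "evseq_sim")
}

# binned parametric session with known ground truth
fixture_parametric_binned <- function(n_neurons = 8, n_trials = 100,
                                      tuning = "gaussian", noise = "none",
                                      seed = 1, ...) {
  set.seed(seed)
  sess <- generate_session(synth_config(n_neurons = n_neurons,
                                        n_trials = n_trials,
                                        tuning = tuning, noise = noise, ...))
  list(session = sess, binned = bin_synth_session(sess))
}
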