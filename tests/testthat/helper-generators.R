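# Shared generators for the test suite.

# Curve observations drawn exactly from the parabolic mean a/t + b with
# i.i.d. Gaussian observation noise: the parameter-recovery design.
sim_parabolic_obs <- function(a, b, n_units, t_max = 10L, noise = 0.01,
                              seed = 1L) {
  set.seed(seed)
  d <- expand.grid(unit_id = sprintf("U%03d", seq_len(n_units)),
                   t = seq_len(t_max), stringsAsFactors = FALSE)
  d$msep <- pmax(0, a / d$t + b + stats::rnorm(nrow(d), 0, noise))
  d
}

# A small hand-built trial table.
make_trials <- function(participant_id, trial_index, set_size, estimate,
                        condition = "novice") {
  data.frame(participant_id = participant_id, trial_index = trial_index,
             set_size = set_size, estimate = estimate, condition = condition,
             stringsAsFactors = FALSE)
}

# First estimate per (participant, set_size), as used by the outer crowds.
first_estimates <- function(records) {
  ord <- order(records$participant_id, records$set_size, records$trial_index)
  r <- records[ord, , drop = FALSE]
  r[!duplicated(r[, c("participant_id", "set_size")]), , drop = FALSE]
}
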