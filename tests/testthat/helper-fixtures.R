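# Small fixtures shared across test files, built in code.

# A 5-day set of sessions whose anticipatory CS+/CS- rates diverge with
# training, emulating acquisition of the association.
make_learning_sessions <- function(n_per_cs = 40, seed = 99) {
  rp <- c(1.0, 2.0, 3.0, 4.0, 5.0)   # CS+ anticipatory rate by day (Hz)
  rm <- c(1.0, 1.2, 1.0, 0.8, 0.6)   # CS- anticipatory rate by day
  lapply(1:5, function(d) {
    tt <- generate_trial_table(n_per_cs, day = d, seed = seed + d)
    generate_licks(tt, rate_plus = rp[d], rate_minus = rm[d],
                   seed = seed + 100 + d)
  })
}

# Brute-force all-pairs auROC oracle (independent of the rank-sum path).
auroc_bruteforce <- function(a, b) {
  wins <- 0
  for (x in a) for (y in b) wins <- wins + (x > y) + 0.5 * (x == y)
  wins / (length(a) * length(b))
}

# A small IT-like dataset: trial table + traces + dff.
make_it_dataset <- function(n_roi = 40, n_per_cs = 20, noise_sd = 0.05,
                            seed = 7, day = 1) {
  tt <- generate_trial_table(n_per_cs, day = day, seed = seed)
  spec <- population_spec(n_roi, "IT_like", noise_sd = noise_sd)
  tr <- generate_roi_traces(tt, spec, seed = seed + 1)
  list(table = tt, traces = tr, dff = compute_dff(tr, tt), spec = spec)
}
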