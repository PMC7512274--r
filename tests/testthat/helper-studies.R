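# study results shared across the acceptance tests; computed once per test
# run, at the desk scale (3 trials, 20-point lambda grid; 2 trials and a
# 30-pair grid for the baseline sweep) with a fixed master seed

.acc_cache <- new.env(parent = emptyenv())

acc_seed <- 1L

acc_oracle_study <- function() {
  if (is.null(.acc_cache$oracle)) {
    .acc_cache$oracle <- run_oracle_study(
      ks_values = c(2, 3, 15), nit_values = c(2, 3, 4), n_trials = 3,
      T = 50000, lambda = seq(0.005, 0.1, by = 0.005), threshold = 1e-3,
      adaptive = TRUE, k = 15, r = 1, p = 1, seed = acc_seed)
  }
  .acc_cache$oracle
}

acc_selection_study <- function() {
  if (is.null(.acc_cache$selection)) {
    .acc_cache$selection <- run_selection_study(
      ks_values = c(2, 3, 15), n_trials = 3, T = 50000,
      lambda = seq(0.005, 0.1, by = 0.005), nit = 2, threshold = 1e-3,
      adaptive = TRUE, k = 15, r = 1, p = 1, seed = acc_seed,
      loops = "constrained")
  }
  .acc_cache$selection
}

acc_sl_study <- function() {
  if (is.null(.acc_cache$sl)) {
    .acc_cache$sl <- run_algosl_study(
      ks_values = c(2, 3, 15), n_trials = 2, T = 50000,
      pairs = study_preset("desk")$sl_pairs, threshold = 1e-3,
      k = 15, r = 1, p = 1, seed = acc_seed)
  }
  .acc_cache$sl
}
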