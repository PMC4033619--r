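# Shared fixtures. Izhikevich integration is the expensive step, so the
# small trial pool used by the experiment tests and the full-scale study
# used by the acceptance checks are each generated once per test run.

test_layout <- function() ensemble_layout(6, 6, 4)
test_stim <- function(...) stimulus_config(trial_duration = 400, ...)

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# 120-trial noise-free pool on a reduced layout / window
test_pool <- function() {
  cached("pool", generate_session(120, test_layout(), test_stim(),
                                  seed = 101))
}

# full-scale paired study at the package defaults (20/20/20 ensembles,
# 2 s windows, 100-trial sessions, pooled data), used by the acceptance
# checks; n_sims trades precision for runtime (SE of each mean ~ 0.6 pp)
acceptance_study <- function() {
  cached("study", run_study(seq(0.5, 1, by = 0.1), n_sims = 150,
                            n_trials = 100, master_seed = 101))
}

study_mean <- function(study, acc, mode) {
  s <- study$summary
  s$mean_perf[s$accuracy == acc & s$mode == mode]
}

# small two-class gaussian-blob session built directly (not via the
# generator) for diagnostic tests
blob_session <- function(n_per_class, sep, sd = 1, n_units = 6, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  labels <- rep(1:2, each = n_per_class)
  shift <- ifelse(labels == 1, 0, sep)
  rates <- matrix(abs(stats::rnorm(n * n_units, 10 + shift, sd)), n, n_units)
  criticgate:::as_session_data(rates, labels)
}
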