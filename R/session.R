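#' Stimulus and integration settings for synthetic sessions
#'
#' Controls how the binary task stimulus is turned into synaptic current and
#' how trials are integrated. Neurons tuned to the trial's motor state receive
#' the on-stimulus (`base_stimulus`); all other neurons receive 0. Every
#' neuron additionally receives Gaussian background current noise. For
#' neurons marked as perturbed, each on/off stimulus value is replaced by a
#' draw from `Normal(noise_mean, noise_sd)` truncated at zero, which weakens
#' and blurs the tuning and makes the two classes overlap.
#'
#' @param dt Euler integration step, ms.
#' @param trial_duration Length of the rate window, ms (defaults to the 2 s
#'   post-cue window used for binned firing rates).
#' @param base_stimulus On-value of the stimulus train.
#' @param current_gain Multiplier mapping stimulus to synaptic current.
#' @param background_current_sd SD of the additive background current.
#' @param noise_fraction Fraction of neurons (tuned ones first) whose stimulus
#'   is replaced by the Gaussian perturbation; between 0 and 1.
#' @param noise_mean,noise_sd Parameters of the perturbing Gaussian.
#' @return An object of class `stimulus_config`.
#' @export
stimulus_config <- function(dt = 0.5, trial_duration = 2000,
                            base_stimulus = 1, current_gain = 10,
                            background_current_sd = 1,
                            noise_fraction = 0, noise_mean = 0.6,
                            noise_sd = 0.2) {
  if (dt <= 0) stop("'dt' must be > 0")
  if (trial_duration <= 0) stop("'trial_duration' must be > 0")
  if (noise_fraction < 0 || noise_fraction > 1)
    stop("'noise_fraction' must lie in [0, 1]")
  structure(list(dt = dt, trial_duration = trial_duration,
                 base_stimulus = base_stimulus, current_gain = current_gain,
                 background_current_sd = background_current_sd,
                 noise_fraction = noise_fraction, noise_mean = noise_mean,
                 noise_sd = noise_sd),
            class = "stimulus_config")
}

#' Ensemble layout of a synthetic population
#'
#' Three ensembles: one tuned to each of the two motor states and one tuned
#' to neither (background activity only), emulating task-unrelated units in
#' real recordings.
#'
#' @param n_tuned_1,n_tuned_2 Neurons tuned to state 1 / state 2.
#' @param n_untuned Neurons tuned to neither state.
#' @return An object of class `ensemble_layout`.
#' @export
ensemble_layout <- function(n_tuned_1 = 20, n_tuned_2 = 20, n_untuned = 20) {
  counts <- c(n_tuned_1, n_tuned_2, n_untuned)
  if (any(counts < 0)) stop("ensemble counts must be >= 0")
  if (sum(counts) < 2) stop("need at least 2 neurons in total")
  structure(list(n_tuned_1 = n_tuned_1, n_tuned_2 = n_tuned_2,
                 n_untuned = n_untuned),
            class = "ensemble_layout")
}

#' @export
format.ensemble_layout <- function(x, ...) {
  sprintf("%d/%d/%d (state-1 / state-2 / untuned)",
          x$n_tuned_1, x$n_tuned_2, x$n_untuned)
}

#' Build the per-step stimulus train for one neuron and trial
#'
#' Neurons tuned to the trial's state receive `base_stimulus` at every step
#' of the window; neurons tuned to the other state and untuned neurons
#' receive 0. If `perturbed`, every value is replaced by an independent draw
#' from `Normal(noise_mean, noise_sd)` truncated at 0, irrespective of the
#' trial label. Background current is *not* part of the train; it is added at
#' integration time as `current_gain * stimulus + Normal(0,
#' background_current_sd)`.
#'
#' @param neuron_role One of `"tuned-1"`, `"tuned-2"`, `"untuned"`.
#' @param trial_label Motor state of the trial, 1 or 2.
#' @param cfg A [stimulus_config()].
#' @param perturbed Whether this neuron's stimulus is noise-perturbed.
#' @return Numeric vector of per-time-step stimulus values.
#' @export
make_stimulus <- function(neuron_role, trial_label, cfg, perturbed = FALSE) {
  if (!neuron_role %in% c("tuned-1", "tuned-2", "untuned"))
    stop("unknown neuron role: ", neuron_role)
  if (!trial_label %in% c(1, 2)) stop("'trial_label' must be 1 or 2")
  n_steps <- round(cfg$trial_duration / cfg$dt)
  if (perturbed) {
    return(pmax(stats::rnorm(n_steps, cfg$noise_mean, cfg$noise_sd), 0))
  }
  on <- (neuron_role == "tuned-1" && trial_label == 1) ||
        (neuron_role == "tuned-2" && trial_label == 2)
  rep(if (on) cfg$base_stimulus else 0, n_steps)
}

# Which neurons carry the Gaussian perturbation: round(noise_fraction * total)
# drawn without replacement, tuned neurons first (the perturbation is meant
# to degrade informative units before touching background ones).
draw_perturbed_set <- function(roles, noise_fraction) {
  n <- length(roles)
  n_pert <- round(noise_fraction * n)
  pert <- rep(FALSE, n)
  if (n_pert > 0) {
    tuned <- which(roles != "untuned")
    untuned <- which(roles == "untuned")
    ord <- c(sample(tuned), sample(untuned))
    pert[ord[seq_len(n_pert)]] <- TRUE
  }
  pert
}

#' Generate a synthetic two-state neural session
#'
#' Simulates every neuron of the layout over each trial window with the
#' Izhikevich model and bins spikes into one firing-rate vector per trial
#' (spike count over the window; normalization is left to the decoder).
#' Trial labels are balanced Bernoulli draws. Neuron parameters are drawn
#' once per session with [draw_excitatory_params()]; the perturbed-neuron
#' set (size `round(noise_fraction * n)`) is drawn once per session.
#'
#' @param n_trials Number of trials; must be positive.
#' @param layout An [ensemble_layout()].
#' @param cfg A [stimulus_config()].
#' @param seed Optional integer seed; with a fixed seed the session is
#'   bit-reproducible.
#' @return An object of class `session_data`: list with `rates` (trials x
#'   neurons spike-count matrix), `labels` (integer vector in \{1, 2\}) and
#'   `meta` (layout, config, seed, roles, perturbed set).
#' @export
#' @examples
#' s <- generate_session(4, ensemble_layout(3, 3, 2),
#'                       stimulus_config(trial_duration = 200), seed = 1)
#' s$rates
generate_session <- function(n_trials, layout = ensemble_layout(),
                             cfg = stimulus_config(), seed = NULL) {
  if (n_trials <= 0) stop("'n_trials' must be > 0")
  n <- layout$n_tuned_1 + layout$n_tuned_2 + layout$n_untuned
  if (n == 0) stop("layout has zero neurons")
  if (!is.null(seed)) set.seed(seed)

  roles <- rep(c("tuned-1", "tuned-2", "untuned"),
               c(layout$n_tuned_1, layout$n_tuned_2, layout$n_untuned))
  params <- draw_excitatory_params(n)
  if (n == 1) params <- list(params)
  cpar <- vapply(params, `[[`, numeric(1), "c")
  dpar <- vapply(params, `[[`, numeric(1), "d")
  pert <- draw_perturbed_set(roles, cfg$noise_fraction)

  labels <- 1L + as.integer(stats::runif(n_trials) < 0.5)
  n_steps <- round(cfg$trial_duration / cfg$dt)
  rates <- matrix(0, n_trials, n)
  colnames(rates) <- sprintf("unit_%04d", seq_len(n))
  for (tr in seq_len(n_trials)) {
    stim <- matrix(0, n, n_steps)
    for (i in seq_len(n)) {
      stim[i, ] <- make_stimulus(roles[i], labels[tr], cfg, pert[i])
    }
    rates[tr, ] <- integrate_trial(stim, a = 0.02, b = 0.2, cpar, dpar,
                                   cfg$current_gain,
                                   cfg$background_current_sd, cfg$dt)
  }
  structure(list(rates = rates, labels = labels,
                 meta = list(layout = layout, cfg = cfg, seed = seed,
                             roles = roles, perturbed = pert)),
            class = "session_data")
}

# Minimal constructor for sessions that do not come from the generator
# (external recordings, test fixtures).
as_session_data <- function(rates, labels, meta = list()) {
  rates <- as.matrix(rates)
  labels <- as.integer(labels)
  if (nrow(rates) != length(labels))
    stop("row count of 'rates' must equal length of 'labels'")
  if (any(rates < 0)) stop("firing rates must be non-negative")
  if (!all(labels %in% c(1L, 2L))) stop("labels must be 1 or 2")
  if (is.null(colnames(rates)))
    colnames(rates) <- sprintf("unit_%04d", seq_len(ncol(rates)))
  structure(list(rates = rates, labels = labels, meta = meta),
            class = "session_data")
}

#' @export
print.session_data <- function(x, ...) {
  cat(sprintf("<session_data> %d trials x %d units\n",
              nrow(x$rates), ncol(x$rates)))
  tab <- table(factor(x$labels, levels = 1:2))
  cat(sprintf("  labels: %d state-1, %d state-2\n", tab[1], tab[2]))
  if (!is.null(x$meta$layout))
    cat("  layout:", format(x$meta$layout), "\n")
  if (!is.null(x$meta$cfg))
    cat(sprintf("  noise_fraction: %g\n", x$meta$cfg$noise_fraction))
  invisible(x)
}

#' Write / read a session as CSV with a metadata sidecar
#'
#' The CSV has one row per trial, columns `unit_0001 ... unit_NNNN` followed
#' by `label` (1 or 2), with a mandatory header. Generation metadata (seed,
#' layout, stimulus settings, perturbed units) goes to a key-value sidecar at
#' `<path>.meta`.
#'
#' @param session A `session_data` object.
#' @param path Output CSV path.
#' @return `write_session` returns `path` invisibly; `read_session` returns a
#'   `session_data`.
#' @export
write_session <- function(session, path) {
  df <- as.data.frame(session$rates)
  df$label <- session$labels
  utils::write.csv(df, path, row.names = FALSE)
  meta <- session$meta
  lines <- character(0)
  add <- function(k, v) sprintf("%s: %s", k, paste(v, collapse = " "))
  if (!is.null(meta$seed)) lines <- c(lines, add("seed", meta$seed))
  if (!is.null(meta$layout))
    lines <- c(lines, add("layout", unlist(meta$layout)))
  if (!is.null(meta$cfg))
    lines <- c(lines, vapply(names(meta$cfg), function(k)
      add(paste0("stimulus.", k), meta$cfg[[k]]), character(1)))
  if (!is.null(meta$perturbed))
    lines <- c(lines, add("perturbed_units", which(meta$perturbed)),
               add("n_perturbed", sum(meta$perturbed)))
  writeLines(lines, paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  load_external_session(path)
}
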