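#' Run one closed-loop decoding session
#'
#' Per trial: normalize the firing-rate vector with the pseudo-real-time
#' normalizer, propagate it through the actor, select the greedy action, get
#' critic feedback on it, and update the weights according to the mode. The
#' actor starts naive (fresh weights and normalizer) unless one is supplied.
#' Session performance is the percentage of trials whose chosen action
#' matches the true label — ground truth, not the critic's (possibly wrong)
#' report.
#'
#' @param session A `session_data` (from [generate_session()] or
#'   [load_external_session()]).
#' @param mode `"plain"` (update every trial) or `"confidence"`.
#' @param critic A [critic_config()].
#' @param actor Optional pre-initialized [init_actor()] network; default is a
#'   fresh one (seeded by `actor_seed` if given).
#' @param actor_seed Seed for the fresh actor initialization.
#' @param confidence_rule,gate Passed to [apply_update()].
#' @param mu_plus,mu_minus Learning rates for the fresh actor.
#' @param feedback_correct Optional logical vector (one per trial) fixing
#'   where the critic is correct; lets paired runs share the same feedback
#'   stream. Default: drawn from `critic`.
#' @param critic_seed Seed for the feedback-correctness draw when
#'   `feedback_correct` is not supplied.
#' @return A `trial_log` data frame with columns `trial`, `label`, `action`,
#'   `correct`, `r`, `rho`, `was_correct`, `updated`, and attributes
#'   `performance` (percent correct) and `mode`.
#' @export
run_session <- function(session, mode = c("plain", "confidence"),
                        critic = critic_config(1.0),
                        actor = NULL, actor_seed = NULL,
                        confidence_rule = c("literal", "gated"), gate = 0.5,
                        mu_plus = 0.005, mu_minus = 0.005,
                        feedback_correct = NULL, critic_seed = NULL) {
  mode <- match.arg(mode)
  confidence_rule <- match.arg(confidence_rule)
  n_trials <- nrow(session$rates)
  if (n_trials == 0) stop("session is empty")
  n_in <- ncol(session$rates)
  if (is.null(actor))
    actor <- init_actor(n_in, mu_plus = mu_plus, mu_minus = mu_minus,
                        seed = actor_seed)
  if (nrow(actor$w_in) != n_in)
    stop("actor input size does not match the session")
  if (is.null(feedback_correct)) {
    if (!is.null(critic_seed)) set.seed(critic_seed)
    feedback_correct <- draw_correct_stream(critic, n_trials)
  }
  if (length(feedback_correct) != n_trials)
    stop("'feedback_correct' must have one entry per trial")
  n_actions <- ncol(actor$w_out)

  w_in <- actor$w_in; w_out <- actor$w_out
  mu_p <- actor$mu_plus; mu_m <- actor$mu_minus
  norm <- actor$norm
  log <- data.frame(trial = seq_len(n_trials), label = session$labels,
                    action = 0L, correct = FALSE, r = 0, rho = 0,
                    was_correct = FALSE, updated = FALSE)
  for (tr in seq_len(n_trials)) {
    nr <- normalize_input(norm, session$rates[tr, ])
    norm <- nr$norm
    f <- forward_raw(w_in, w_out, nr$x)
    lab <- session$labels[tr]
    ok <- f$action == lab
    fb <- critic_evaluate(f$action, lab, critic, n_actions = n_actions,
                          correct = feedback_correct[tr])
    d_h <- layer_delta(f$x_h, f$P_h, fb, mode, confidence_rule, gate,
                       mu_p, mu_m)
    d_o <- layer_delta(f$x_o, f$P_o, fb, mode, confidence_rule, gate,
                       mu_p, mu_m)
    updated <- any(d_h != 0) || any(d_o != 0)
    if (updated) {
      w_in <- w_in + outer(nr$x, d_h)
      w_out <- w_out + outer(f$x_h, d_o)
    }
    log$action[tr] <- f$action; log$correct[tr] <- ok
    log$r[tr] <- fb$r; log$rho[tr] <- fb$rho
    log$was_correct[tr] <- fb$was_correct; log$updated[tr] <- updated
  }
  structure(log, class = c("trial_log", "data.frame"),
            performance = 100 * mean(log$correct), mode = mode)
}

#' Session performance of a trial log
#' @param log A `trial_log`.
#' @return Percent correct actions over the session.
#' @export
performance <- function(log) attr(log, "performance")

# sample a balanced session out of a pre-generated trial pool (with
# replacement across trials, label-matched per trial)
sample_pool_session <- function(pool, n_trials) {
  labels <- 1L + as.integer(stats::runif(n_trials) < 0.5)
  by_label <- list(which(pool$labels == 1L), which(pool$labels == 2L))
  if (any(lengths(by_label) == 0))
    stop("trial pool lacks one of the two classes")
  idx <- vapply(labels, function(l) {
    cand <- by_label[[l]]
    cand[sample.int(length(cand), 1)]
  }, integer(1))
  as_session_data(pool$rates[idx, , drop = FALSE], labels,
                  meta = list(pooled = TRUE, cfg = pool$meta$cfg,
                              layout = pool$meta$layout))
}

#' Monte Carlo study over a critic-accuracy grid
#'
#' For every accuracy on the grid, `n_sims` sessions are run in each update
#' mode. The two modes are paired: within a simulation they share the same
#' neural data, trial order, actor initialization and feedback-correctness
#' stream, so their difference isolates the update rule. By default neural
#' data comes from one pre-generated trial pool per study (`pooled = TRUE`;
#' sessions sample label-matched trials from it), since the Izhikevich
#' integration dominates runtime; `pooled = FALSE` generates a fresh session
#' per simulation.
#'
#' @param accuracy_grid Critic accuracies, each in `[0, 1]`.
#' @param n_sims Simulations (sessions) per accuracy; at least 2.
#' @param n_trials Trials per session.
#' @param layout,cfg Data-generation settings ([ensemble_layout()],
#'   [stimulus_config()]).
#' @param modes Update modes to run (subset of `"plain"`, `"confidence"`).
#' @param master_seed Single seed from which all randomness flows.
#' @param confidence_rule,gate Confidence rule for the `"confidence"` mode.
#' @param mu_plus,mu_minus Actor learning rates.
#' @param pooled Use the pooled-data mode (default) or fresh sessions.
#' @param pool_size Trials in the pre-generated pool.
#' @param alpha Significance level of the paired comparison between modes.
#' @param stability_windows Terminal windows (in trials) for the stability
#'   counts.
#' @return A `study_result`: list with `summary` (tidy data frame: accuracy,
#'   mode, noise_fraction, n_sims, mean_perf, sd_perf, stability columns,
#'   t_stat, p_value), `performances` (n_sims x mode x accuracy array),
#'   `config`, `master_seed` and `config_hash`.
#' @export
#' @examples
#' \donttest{
#' r <- run_study(c(0.6, 1.0), n_sims = 5, n_trials = 20,
#'                layout = ensemble_layout(4, 4, 2),
#'                cfg = stimulus_config(trial_duration = 200),
#'                master_seed = 7)
#' r$summary
#' }
run_study <- function(accuracy_grid = seq(0.5, 1, by = 0.1), n_sims = 200,
                      n_trials = 100, layout = ensemble_layout(),
                      cfg = stimulus_config(),
                      modes = c("plain", "confidence"), master_seed = 1,
                      confidence_rule = c("literal", "gated"), gate = 0.5,
                      mu_plus = 0.005, mu_minus = 0.005,
                      pooled = TRUE, pool_size = 3 * n_trials,
                      alpha = 0.001, stability_windows = c(50, 30)) {
  confidence_rule <- match.arg(confidence_rule)
  stopifnot(n_sims >= 2, all(accuracy_grid >= 0), all(accuracy_grid <= 1))
  modes <- match.arg(modes, c("plain", "confidence"), several.ok = TRUE)
  stability_windows <- stability_windows[stability_windows <= n_trials]

  set.seed(master_seed)
  pool_seed <- sample.int(.Machine$integer.max, 1)
  sim_seeds <- matrix(sample.int(.Machine$integer.max,
                                 n_sims * length(accuracy_grid)),
                      n_sims, length(accuracy_grid))
  pool <- if (pooled) generate_session(pool_size, layout, cfg,
                                       seed = pool_seed) else NULL

  n_in <- layout$n_tuned_1 + layout$n_tuned_2 + layout$n_untuned
  perf <- array(NA_real_, c(n_sims, length(modes), length(accuracy_grid)),
                dimnames = list(NULL, modes, accuracy_grid))
  stab <- array(0L, c(length(stability_windows), length(modes),
                      length(accuracy_grid)),
                dimnames = list(stability_windows, modes, accuracy_grid))
  for (ai in seq_along(accuracy_grid)) {
    critic <- critic_config(accuracy_grid[ai])
    for (s in seq_len(n_sims)) {
      set.seed(sim_seeds[s, ai])
      session <- if (pooled) sample_pool_session(pool, n_trials)
                 else generate_session(n_trials, layout, cfg)
      actor <- init_actor(n_in, mu_plus = mu_plus, mu_minus = mu_minus)
      stream <- draw_correct_stream(critic, n_trials)
      for (mi in seq_along(modes)) {
        log <- run_session(session, modes[mi], critic, actor = actor,
                           confidence_rule = confidence_rule, gate = gate,
                           feedback_correct = stream)
        perf[s, mi, ai] <- performance(log)
        for (wi in seq_along(stability_windows)) {
          w <- stability_windows[wi]
          if (all(log$correct[(n_trials - w + 1):n_trials]))
            stab[wi, mi, ai] <- stab[wi, mi, ai] + 1L
        }
      }
    }
  }

  config <- list(accuracy_grid = accuracy_grid, n_sims = n_sims,
                 n_trials = n_trials, layout = unclass(layout),
                 cfg = unclass(cfg), modes = modes,
                 confidence_rule = confidence_rule, gate = gate,
                 mu_plus = mu_plus, mu_minus = mu_minus, pooled = pooled,
                 pool_size = pool_size, alpha = alpha,
                 stability_windows = stability_windows)
  rows <- list()
  for (ai in seq_along(accuracy_grid)) {
    tt <- list(t = NA_real_, p = NA_real_)
    if (all(c("plain", "confidence") %in% modes)) {
      tt <- tryCatch(
        paired_comparison(perf[, "confidence", ai], perf[, "plain", ai],
                          alpha = alpha),
        error = function(e) list(t = NA_real_, p = NA_real_))
    }
    for (mi in seq_along(modes)) {
      row <- data.frame(accuracy = accuracy_grid[ai], mode = modes[mi],
                        noise_fraction = cfg$noise_fraction, n_sims = n_sims,
                        mean_perf = mean(perf[, mi, ai]),
                        sd_perf = stats::sd(perf[, mi, ai]),
                        t_stat = tt$t, p_value = tt$p)
      for (wi in seq_along(stability_windows))
        row[[paste0("stable_", stability_windows[wi])]] <- stab[wi, mi, ai]
      rows[[length(rows) + 1]] <- row
    }
  }
  summary <- do.call(rbind, rows)
  structure(list(summary = summary, performances = perf,
                 stability = stab, config = config,
                 master_seed = master_seed,
                 config_hash = config_hash(config)),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> master_seed=%d, config_hash=%s\n",
              x$master_seed, x$config_hash))
  print(x$summary, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Count stable (converged) sessions
#'
#' A session counts as stable for a window if every one of its final
#' `window` trials was a correct action, i.e. it reached and maintained 100%
#' accuracy to the end of the session.
#'
#' @param logs A list of `trial_log` objects (see [run_session()]).
#' @param windows Terminal window lengths in trials.
#' @return Named integer vector of stable-session counts per window.
#' @export
stability_counts <- function(logs, windows = c(50, 30)) {
  if (inherits(logs, "trial_log")) logs <- list(logs)
  n_trials <- vapply(logs, nrow, integer(1))
  if (any(windows > min(n_trials)))
    stop("stability window longer than the shortest session")
  counts <- vapply(windows, function(w) {
    sum(vapply(logs, function(lg) {
      n <- nrow(lg)
      all(lg$correct[(n - w + 1):n])
    }, logical(1)))
  }, integer(1))
  stats::setNames(counts, paste0("stable_", windows))
}

#' Paired comparison of per-simulation performances
#'
#' Student's paired t-test on the per-simulation performance differences of
#' two systems run on shared streams (two-tailed).
#'
#' @param perf_a,perf_b Equal-length performance vectors, paired by
#'   simulation.
#' @param alpha Significance level (default 0.001).
#' @return List with `t`, `p`, `significant`, `alpha` and `mean_diff`.
#' @export
paired_comparison <- function(perf_a, perf_b, alpha = 0.001) {
  if (length(perf_a) != length(perf_b))
    stop("performance vectors must have equal length")
  d <- perf_a - perf_b
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(list(t = 0, p = 1, significant = FALSE, alpha = alpha,
                  mean_diff = 0))
    stop("degenerate paired sample: constant non-zero difference")
  }
  tt <- stats::t.test(perf_a, perf_b, paired = TRUE,
                      alternative = "two.sided")
  list(t = unname(tt$statistic), p = tt$p.value,
       significant = tt$p.value < alpha, alpha = alpha,
       mean_diff = unname(tt$estimate))
}

#' Class-overlap diagnostic in the principal-component plane
#'
#' Projects the session's rate vectors onto their first two principal
#' components and scores how much the two classes overlap there: the error
#' rate of a nearest-class-centroid rule in that plane. Near 0 for well
#' separated classes, near 0.5 when the class distributions are
#' indistinguishable. A monotone diagnostic only — not a decoder.
#'
#' @param session A `session_data` with at least 2 trials per class.
#' @return Overlap score in `[0, 1]` (values near 0.5 mean full overlap).
#' @export
class_overlap_diagnostic <- function(session) {
  labs <- session$labels
  if (any(table(factor(labs, levels = 1:2)) < 2))
    stop("need at least 2 trials per class")
  rates <- session$rates
  if (all(apply(rates, 2, stats::sd) == 0))
    stop("degenerate session: all units have zero variance")
  pc <- stats::prcomp(rates, center = TRUE, scale. = FALSE)
  k <- min(2, ncol(pc$x))
  z <- pc$x[, seq_len(k), drop = FALSE]
  c1 <- colMeans(z[labs == 1L, , drop = FALSE])
  c2 <- colMeans(z[labs == 2L, , drop = FALSE])
  d1 <- rowSums(sweep(z, 2, c1)^2)
  d2 <- rowSums(sweep(z, 2, c2)^2)
  pred <- ifelse(d1 <= d2, 1L, 2L)
  mean(pred != labs)
}

#' Sweep stimulus-noise levels
#'
#' Runs [run_study()] once per noise level (fraction of neurons whose
#' stimulus is replaced by the Gaussian perturbation), producing the
#' performance-versus-accuracy table per noise level.
#'
#' @param noise_grid Noise fractions, each in `[0, 1]`.
#' @param accuracy_grid,n_sims,n_trials,layout,cfg,modes Passed to
#'   [run_study()].
#' @param master_seed Seed from which each noise level's study seed derives.
#' @param ... Further arguments to [run_study()].
#' @return A `noise_sweep_result`: list with `summary` (row-bound study
#'   summaries, one `noise_fraction` per block) and `studies` (the
#'   individual `study_result`s, named by noise level).
#' @export
noise_sweep <- function(noise_grid = seq(0, 1, by = 0.1),
                        accuracy_grid = seq(0.5, 1, by = 0.1),
                        n_sims = 200, n_trials = 100,
                        layout = ensemble_layout(), cfg = stimulus_config(),
                        modes = c("plain", "confidence"), master_seed = 1,
                        ...) {
  stopifnot(all(noise_grid >= 0), all(noise_grid <= 1))
  set.seed(master_seed)
  seeds <- sample.int(.Machine$integer.max, length(noise_grid))
  studies <- lapply(seq_along(noise_grid), function(i) {
    cfg_i <- cfg
    cfg_i$noise_fraction <- noise_grid[i]
    run_study(accuracy_grid, n_sims, n_trials, layout, cfg_i, modes,
              master_seed = seeds[i], ...)
  })
  names(studies) <- noise_grid
  summary <- do.call(rbind, lapply(studies, `[[`, "summary"))
  rownames(summary) <- NULL
  structure(list(summary = summary, studies = studies,
                 master_seed = master_seed),
            class = "noise_sweep_result")
}

#' @export
print.noise_sweep_result <- function(x, ...) {
  cat(sprintf("<noise_sweep_result> %d noise levels, master_seed=%d\n",
              length(x$studies), x$master_seed))
  print(x$summary, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Write study outputs
#'
#' Writes the tidy summary CSV and a JSON sidecar carrying the full
#' configuration, master seed and config hash for provenance.
#'
#' @param result A `study_result` or `noise_sweep_result`.
#' @param csv_path,json_path Output paths; `json_path = NULL` derives it
#'   from `csv_path`.
#' @export
write_study_result <- function(result, csv_path, json_path = NULL) {
  if (is.null(json_path)) json_path <- sub("\\.csv$", ".json", csv_path)
  utils::write.csv(result$summary, csv_path, row.names = FALSE)
  meta <- if (inherits(result, "study_result")) {
    list(master_seed = result$master_seed, config_hash = result$config_hash,
         config = result$config)
  } else {
    list(master_seed = result$master_seed,
         studies = lapply(result$studies, function(s)
           list(master_seed = s$master_seed, config_hash = s$config_hash,
                config = s$config)))
  }
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(csv_path)
}

#' Write a per-session trial log as CSV
#' @param log A `trial_log`.
#' @param path Output CSV path.
#' @export
write_trial_log <- function(log, path) {
  utils::write.csv(as.data.frame(log), path, row.names = FALSE)
  invisible(path)
}
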