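#' Simulated critic of parametric accuracy
#'
#' An N-accurate critic gives correct evaluative feedback with probability N
#' and the negated feedback otherwise. Alongside the reward value it emits a
#' boolean confidence that is 1 exactly when the feedback is correct — the
#' simulation protocol in which the actor never learns N itself but knows,
#' trial by trial, whether the feedback can be trusted.
#'
#' @param accuracy Probability that the feedback matches the truth; in
#'   `[0, 1]` (experiments sweep 0.5 to 1).
#' @param quota If `TRUE`, correctness is not i.i.d. but drawn as an exact
#'   quota: in a block of `n` trials, exactly `round(accuracy * n)` are
#'   correct, in random order (useful for single-session traces). Default is
#'   i.i.d. Bernoulli.
#' @return An object of class `critic_config`.
#' @export
critic_config <- function(accuracy, quota = FALSE) {
  if (accuracy < 0 || accuracy > 1) stop("'accuracy' must lie in [0, 1]")
  structure(list(accuracy = accuracy, quota = quota),
            class = "critic_config")
}

# correctness stream for a session: TRUE where the critic will be correct
draw_correct_stream <- function(cfg, n_trials) {
  if (isTRUE(cfg$quota)) {
    k <- round(cfg$accuracy * n_trials)
    sample(rep(c(TRUE, FALSE), c(k, n_trials - k)))
  } else {
    stats::runif(n_trials) < cfg$accuracy
  }
}

#' Evaluate one action
#'
#' Ground truth is `+1` if the selected action matches the correct one, else
#' `-1`. With probability `accuracy` the critic reports the truth with
#' confidence `rho = 1`; otherwise it reports the negated value with
#' `rho = 0`.
#'
#' @param selected_action,correct_action Action indices.
#' @param cfg A [critic_config()].
#' @param n_actions Size of the valid action set.
#' @param correct Optional logical overriding the random correctness draw
#'   (used to share feedback streams across paired runs).
#' @return An object of class `feedback`: list with `r` (-1/+1), `rho` (0/1)
#'   and `was_correct` (logical; for logging only — it duplicates `rho` by
#'   construction and is never shown to the actor's policy).
#' @export
#' @examples
#' critic_evaluate(1, 1, critic_config(1.0))   # r = +1, rho = 1
critic_evaluate <- function(selected_action, correct_action, cfg,
                            n_actions = 2, correct = NULL) {
  ok_set <- seq_len(n_actions)
  if (!(selected_action %in% ok_set) || !(correct_action %in% ok_set))
    stop("action index outside the valid action set")
  truth <- if (selected_action == correct_action) 1 else -1
  if (is.null(correct)) correct <- stats::runif(1) < cfg$accuracy
  structure(list(r = if (correct) truth else -truth,
                 rho = as.numeric(correct),
                 was_correct = correct),
            class = "feedback")
}
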