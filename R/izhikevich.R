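#' Izhikevich neuron parameters
#'
#' Bundles the four parameters of the two-variable Izhikevich spiking model:
#' `a` (recovery time scale, per ms), `b` (recovery sensitivity), `c`
#' (after-spike reset voltage, mV) and `d` (after-spike recovery increment).
#'
#' @param a Recovery time scale; must be positive.
#' @param b Recovery sensitivity; must be positive.
#' @param c After-spike reset voltage in mV; must lie below the +30 mV apex.
#' @param d After-spike recovery increment.
#' @return An object of class `neuron_params`.
#' @seealso [draw_excitatory_params()], [izhikevich_step()]
#' @export
#' @examples
#' neuron_params()  # regular-spiking excitatory defaults
neuron_params <- function(a = 0.02, b = 0.2, c = -65, d = 8) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c), is.numeric(d))
  if (a <= 0) stop("'a' must be > 0")
  if (b <= 0) stop("'b' must be > 0")
  if (c >= 30) stop("reset voltage 'c' must be below the spike apex (30 mV)")
  structure(list(a = a, b = b, c = c, d = d), class = "neuron_params")
}

#' Draw randomized excitatory-cell parameters
#'
#' Samples the standard heterogeneous excitatory parameter set: `a = 0.02`
#' and `b = 0.2` are fixed, while `(c, d) = (-65, 8) + (15, -6) * e^2` with
#' `e ~ Uniform(0, 1)` drawn once per neuron. `e = 0` gives a regular-spiking
#' cell, `e = 1` a chattering cell.
#'
#' @param n Number of neurons to draw.
#' @return For `n = 1` a `neuron_params` object; for `n > 1` a list of them.
#' @export
#' @examples
#' set.seed(1)
#' draw_excitatory_params()
draw_excitatory_params <- function(n = 1) {
  stopifnot(n >= 1)
  e <- stats::runif(n)
  ps <- lapply(e, function(ei) neuron_params(a = 0.02, b = 0.2,
                                             c = -65 + 15 * ei^2,
                                             d = 8 - 6 * ei^2))
  if (n == 1) ps[[1]] else ps
}

#' Advance one Izhikevich neuron by one Euler step
#'
#' Forward-Euler integration of the quadratic membrane equation
#' `v' = 0.04 v^2 + 5 v + 140 - u + I` and the recovery equation
#' `u' = a (b v - u)`, both evaluated at the incoming state. If the advanced
#' membrane potential reaches the +30 mV apex the step reports a spike and
#' applies the after-spike reset `v <- c`, `u <- u + d`; the spike is
#' attributed to the step in which the apex was reached.
#'
#' @param state Named list or vector with elements `v` (membrane potential,
#'   mV) and `u` (recovery variable).
#' @param params A [neuron_params()] object.
#' @param I Synaptic input current for this step.
#' @param dt Integration step in ms; must be positive.
#' @param neuron,step Optional identifiers used in error diagnostics.
#' @return A list with `state` (the advanced, possibly reset, `v`/`u`) and
#'   `spiked` (logical).
#' @export
#' @examples
#' p <- neuron_params()
#' st <- list(v = -70, u = -14)           # rest fixed point at I = 0
#' izhikevich_step(st, p, I = 0, dt = 0.5)
izhikevich_step <- function(state, params, I, dt, neuron = NA, step = NA) {
  if (!is.numeric(dt) || dt <= 0) stop("'dt' must be > 0")
  v <- state$v; u <- state$u
  if (!all(is.finite(c(v, u, I)))) {
    stop(sprintf("non-finite v/u/I (v=%s, u=%s, I=%s) at neuron %s, step %s",
                 format(v), format(u), format(I),
                 as.character(neuron), as.character(step)))
  }
  v_new <- v + dt * (0.04 * v^2 + 5 * v + 140 - u + I)
  u_new <- u + dt * params$a * (params$b * v - u)
  spiked <- v_new >= 30
  if (spiked) {
    v_new <- params$c
    u_new <- u_new + params$d
  }
  list(state = list(v = v_new, u = u_new), spiked = spiked)
}

# Vectorized trial integrator used by generate_session(): all neurons advance
# together over the window; `stim` is an n_neurons x n_steps matrix of
# stimulus values already chosen per neuron and step. Returns spike counts
# per neuron. Same dynamics as izhikevich_step(), kept in lockstep by the
# cross-check in the test suite.
integrate_trial <- function(stim, a, b, cpar, dpar, current_gain,
                            background_current_sd, dt) {
  n <- nrow(stim)
  n_steps <- ncol(stim)
  v <- rep(-70, n)
  u <- b * v
  counts <- integer(n)
  for (s in seq_len(n_steps)) {
    I <- current_gain * stim[, s] + stats::rnorm(n, 0, background_current_sd)
    v_new <- v + dt * (0.04 * v^2 + 5 * v + 140 - u + I)
    u_new <- u + dt * a * (b * v - u)
    sp <- v_new >= 30
    if (any(sp)) {
      counts[sp] <- counts[sp] + 1L
      v_new[sp] <- cpar[sp]
      u_new[sp] <- u_new[sp] + dpar[sp]
    }
    v <- v_new
    u <- u_new
    if (!all(is.finite(v))) {
      stop(sprintf("non-finite membrane potential at neuron %d, step %d",
                   which(!is.finite(v))[1], s))
    }
  }
  counts
}
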