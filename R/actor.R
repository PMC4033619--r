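#' Initialize the actor network
#'
#' The actor is a fully connected three-layer network of binary processing
#' elements: `n_inputs` firing-rate inputs, a hidden layer (5 nodes by
#' default) and one output node per action. Every node computes
#' `P_j = tanh(sum_i w_ij x_i)` and emits the signed output
#' `x_j = sgn(P_j)` (with `sgn(0) = +1`); the action is chosen greedily as
#' the output node with the largest activation. Weights start at small
#' i.i.d. `Uniform(-w0, w0)` values ("naive state"); the input normalizer
#' starts empty.
#'
#' @param n_inputs Number of neural inputs.
#' @param n_hidden Hidden-layer size.
#' @param n_actions Number of actions (output nodes), at least 2.
#' @param w0 Half-width of the uniform weight initialization.
#' @param mu_plus,mu_minus Learning rates of the reward and penalty terms of
#'   the update rule.
#' @param seed Optional seed for reproducible initialization.
#' @return An object of class `actor_network` with weight matrices `w_in`
#'   (`n_inputs x n_hidden`), `w_out` (`n_hidden x n_actions`), the learning
#'   rates and a fresh [new_normalizer()] state.
#' @export
#' @examples
#' a <- init_actor(60, seed = 1)
#' dim(a$w_in); dim(a$w_out)
init_actor <- function(n_inputs, n_hidden = 5, n_actions = 2, w0 = 0.1,
                       mu_plus = 0.005, mu_minus = 0.005, seed = NULL) {
  stopifnot(n_inputs >= 1, n_hidden >= 1, n_actions >= 2)
  if (mu_plus < 0 || mu_minus < 0) stop("learning rates must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  structure(list(
    w_in = matrix(stats::runif(n_inputs * n_hidden, -w0, w0),
                  n_inputs, n_hidden),
    w_out = matrix(stats::runif(n_hidden * n_actions, -w0, w0),
                   n_hidden, n_actions),
    mu_plus = mu_plus, mu_minus = mu_minus,
    norm = new_normalizer(n_inputs)
  ), class = "actor_network")
}

#' @export
print.actor_network <- function(x, ...) {
  cat(sprintf("<actor_network> %d inputs -> %d hidden -> %d actions\n",
              nrow(x$w_in), ncol(x$w_in), ncol(x$w_out)))
  cat(sprintf("  mu+ = %g, mu- = %g\n", x$mu_plus, x$mu_minus))
  invisible(x)
}

#' Pseudo-real-time input normalizer
#'
#' The decoder starts naive, so inputs are scaled on line: a running record
#' of the highest firing rate seen on each input divides that input, keeping
#' every normalized value in `[0, 1]` without any pre-session calibration.
#' State carries across trials within a session and is reset between
#' sessions. Inputs that have never fired map to 0 (floor guard, no division
#' blow-up).
#'
#' @param n_inputs Number of inputs tracked.
#' @param floor Minimum divisor guard; must be positive.
#' @return `new_normalizer` returns a `normalizer` object.
#' @export
new_normalizer <- function(n_inputs, floor = 1e-12) {
  stopifnot(n_inputs >= 1, floor > 0)
  structure(list(running_max = rep(0, n_inputs), floor = floor),
            class = "normalizer")
}

#' @rdname new_normalizer
#' @param norm A `normalizer` object.
#' @param raw_rates Non-negative firing-rate vector for one trial.
#' @return `normalize_input` returns a list with the updated `norm` and the
#'   normalized vector `x` in `[0, 1]`.
#' @export
#' @examples
#' nz <- new_normalizer(1)
#' for (r in c(2, 4, 3)) {
#'   res <- normalize_input(nz, r); nz <- res$norm
#'   print(res$x)   # 1.0, 1.0, 0.75
#' }
normalize_input <- function(norm, raw_rates) {
  if (any(raw_rates < 0)) stop("firing rates must be non-negative")
  if (length(raw_rates) != length(norm$running_max))
    stop("input length does not match normalizer state")
  norm$running_max <- pmax(norm$running_max, raw_rates)
  x <- raw_rates / pmax(norm$running_max, norm$floor)
  x[norm$running_max == 0] <- 0
  list(norm = norm, x = x)
}

# sign convention of the binary nodes: sgn(0) = +1
sgn <- function(p) ifelse(p >= 0, 1, -1)

# bare forward pass shared by actor_forward() and the session loop
forward_raw <- function(w_in, w_out, x_in) {
  P_h <- tanh(drop(x_in %*% w_in))
  x_h <- sgn(P_h)
  P_o <- tanh(drop(x_h %*% w_out))
  list(P_h = P_h, x_h = x_h, P_o = P_o, x_o = sgn(P_o),
       action = which.max(P_o))
}

#' Forward pass and greedy action selection
#'
#' Propagates a normalized input through the network: hidden activations
#' `P = tanh(x_in %*% w_in)` with signed outputs `x = sgn(P)`; the output
#' layer consumes the hidden *signed* outputs, `P = tanh(x_h %*% w_out)`.
#' The greedy policy picks the output node with the highest activation;
#' ties break toward the lowest index.
#'
#' @param actor An [init_actor()] network.
#' @param x_in Normalized input vector (length `n_inputs`).
#' @return A list with `hidden` and `output` (each holding `P` and `x`) and
#'   the selected `action`.
#' @export
actor_forward <- function(actor, x_in) {
  if (length(x_in) != nrow(actor$w_in))
    stop(sprintf("input has length %d but the actor expects %d",
                 length(x_in), nrow(actor$w_in)))
  f <- forward_raw(actor$w_in, actor$w_out, x_in)
  list(hidden = list(P = f$P_h, x = f$x_h),
       output = list(P = f$P_o, x = f$x_o),
       action = f$action)
}

#' Hebbian reward-penalty weight increment
#'
#' The associative reward-penalty rule: for a synapse with presynaptic value
#' `x_i`, postsynaptic signed output `x_j` and activation `P_j`, and global
#' reward `r` in \{-1, +1\},
#' `delta = mu_plus * r * (x_j - P_j) * x_i +
#'          mu_minus * (1 - r) * (1 - x_j - P_j) * x_i`.
#' At `r = 1` only the reward term remains and vanishes as `P_j` approaches
#' `x_j` (consolidation); at `r = -1` both terms act and the change is larger
#' — the rule is more sensitive to negative feedback.
#'
#' @param x_i Presynaptic value(s).
#' @param x_j Postsynaptic signed output(s), in \{-1, +1\}.
#' @param P_j Postsynaptic activation(s), in (-1, 1).
#' @param r Reward, -1 or +1.
#' @param mu_plus,mu_minus Reward / penalty learning rates.
#' @return Weight increment(s), vectorized over the arguments.
#' @export
#' @examples
#' hrl_delta(1, 1, 0.5, r = 1,  mu_plus = 0.1, mu_minus = 0.1)  #  0.05
#' hrl_delta(1, 1, 0.5, r = -1, mu_plus = 0.1, mu_minus = 0.1)  # -0.15
hrl_delta <- function(x_i, x_j, P_j, r, mu_plus, mu_minus) {
  stopifnot(r %in% c(-1, 1))
  mu_plus * r * (x_j - P_j) * x_i + mu_minus * (1 - r) * (1 - x_j - P_j) * x_i
}

#' Confidence-weighted weight increment
#'
#' Adds the critic's confidence `rho` to the reward-penalty rule. Two
#' readings are provided:
#'
#' * `mode = "literal"` (default): the algebraic rule
#'   `delta = mu_plus * rho * r * (x_j - P_j) * x_i +
#'            mu_minus * (1 - rho * r) * (1 - x_j - P_j) * x_i`.
#'   At `rho = 1` this reduces exactly to [hrl_delta()]; at `rho = 0` the
#'   reward term vanishes but a penalty-like term survives, so low-confidence
#'   trials still perturb the network. This is the canonical rule here: the
#'   surviving term is what produces the characteristic behavior of the
#'   confidence-weighted decoder at low critic accuracy (see the package
#'   vignette).
#' * `mode = "gated"`: a hard gate — the full [hrl_delta()] when `rho`
#'   exceeds `gate` (default 0.5) and exactly 0 otherwise, i.e. no adaptation
#'   at all on low-confidence trials.
#'
#' @inheritParams hrl_delta
#' @param rho Confidence in the feedback, in `[0, 1]`.
#' @param mode `"literal"` or `"gated"`.
#' @param gate Gate threshold for `mode = "gated"`.
#' @return Weight increment(s).
#' @export
#' @examples
#' # rho = 1: both modes coincide with the plain rule
#' hrl_delta_conf(1, 1, 0.5, r = 1, rho = 1, mu_plus = 0.1, mu_minus = 0.1)
#' # rho = 0, gated: frozen
#' hrl_delta_conf(1, 1, 0.5, r = 1, rho = 0, mu_plus = 0.1, mu_minus = 0.1,
#'                mode = "gated")
hrl_delta_conf <- function(x_i, x_j, P_j, r, rho, mu_plus, mu_minus,
                           mode = c("literal", "gated"), gate = 0.5) {
  mode <- match.arg(mode)
  if (any(rho < 0) || any(rho > 1)) stop("'rho' must lie in [0, 1]")
  if (mode == "gated") {
    if (rho > gate) hrl_delta(x_i, x_j, P_j, r, mu_plus, mu_minus)
    else 0 * x_i * x_j * P_j  # zero, broadcast to the argument shape
  } else {
    mu_plus * rho * r * (x_j - P_j) * x_i +
      mu_minus * (1 - rho * r) * (1 - x_j - P_j) * x_i
  }
}

# per-node delta vectors for a whole layer (x_i is applied by outer product)
layer_delta <- function(x_j, P_j, feedback, mode, confidence_rule, gate,
                        mu_plus, mu_minus) {
  if (mode == "plain") {
    hrl_delta(1, x_j, P_j, feedback$r, mu_plus, mu_minus)
  } else {
    hrl_delta_conf(1, x_j, P_j, feedback$r, feedback$rho, mu_plus, mu_minus,
                   mode = confidence_rule, gate = gate)
  }
}

#' Apply one trial's feedback to every weight
#'
#' Both layers receive the same global feedback `(r, rho)`; each synapse uses
#' only its local values — the normalized input (input-to-hidden) or the
#' hidden signed output (hidden-to-output) as `x_i`, and its postsynaptic
#' node's `x_j`, `P_j`. One-trial memory only: the update uses this trial's
#' activations and nothing else.
#'
#' @param actor An [init_actor()] network.
#' @param acts Activations from [actor_forward()] on this actor.
#' @param x_in The normalized input that produced `acts`.
#' @param feedback A list with reward `r` (and `rho` in confidence mode),
#'   e.g. from [critic_evaluate()].
#' @param mode `"plain"` (update every trial) or `"confidence"`
#'   (confidence-weighted update).
#' @param confidence_rule Which confidence rule to use in confidence mode;
#'   see [hrl_delta_conf()].
#' @param gate Gate threshold for the `"gated"` rule.
#' @return The updated `actor_network`.
#' @export
apply_update <- function(actor, acts, x_in, feedback,
                         mode = c("plain", "confidence"),
                         confidence_rule = c("literal", "gated"),
                         gate = 0.5) {
  mode <- match.arg(mode)
  confidence_rule <- match.arg(confidence_rule)
  if (mode == "confidence" && is.null(feedback$rho))
    stop("confidence mode requires feedback with a 'rho' field")
  d_h <- layer_delta(acts$hidden$x, acts$hidden$P, feedback, mode,
                     confidence_rule, gate, actor$mu_plus, actor$mu_minus)
  d_o <- layer_delta(acts$output$x, acts$output$P, feedback, mode,
                     confidence_rule, gate, actor$mu_plus, actor$mu_minus)
  actor$w_in <- actor$w_in + outer(x_in, d_h)
  actor$w_out <- actor$w_out + outer(acts$hidden$x, d_o)
  actor
}

#' Write / read an actor snapshot as plain text
#'
#' Round-trip exact serialization of the weight matrices and learning rates:
#' one header line per block, then the matrix rows at full precision.
#'
#' @param actor An `actor_network`.
#' @param path Output file.
#' @export
write_actor <- function(actor, path) {
  con <- file(path, "w")
  on.exit(close(con))
  dump_mat <- function(name, m) {
    writeLines(sprintf("# %s %d %d", name, nrow(m), ncol(m)), con)
    utils::write.table(format(m, digits = 17, scientific = TRUE), con,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  writeLines(sprintf("# actor_network mu_plus=%.17g mu_minus=%.17g",
                     actor$mu_plus, actor$mu_minus), con)
  dump_mat("w_in", actor$w_in)
  dump_mat("w_out", actor$w_out)
  invisible(path)
}

#' @rdname write_actor
#' @export
read_actor <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(sub("^# actor_network ", "", lines[1]), " ")[[1]]
  mu <- as.numeric(sub(".*=", "", hdr))
  read_block <- function(at) {
    dims <- as.integer(strsplit(lines[at], " ")[[1]][3:4])
    vals <- as.numeric(unlist(strsplit(trimws(
      lines[(at + 1):(at + dims[1])]), "\\s+")))
    matrix(vals, dims[1], dims[2], byrow = TRUE)
  }
  starts <- grep("^# w_", lines)
  actor <- structure(list(
    w_in = read_block(starts[1]), w_out = read_block(starts[2]),
    mu_plus = mu[1], mu_minus = mu[2], norm = NULL
  ), class = "actor_network")
  actor$norm <- new_normalizer(nrow(actor$w_in))
  actor
}
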