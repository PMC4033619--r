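---
title: "Confidence-weighted Hebbian actor-critic decoding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confidence-weighted Hebbian actor-critic decoding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of the science it implements: the
decoder model and its update rules, the simulated critic, the synthetic
neural data generator, the study design, and the numerical and design
choices made where the method itself leaves them open.

## The decoding problem

A two-choice brain-machine interface must map a vector of binned firing
rates to one of two actions, with no kinematic training signal. In the
actor-critic framing the *actor* is the decoder and the *critic* supplies a
per-trial evaluative reward `r = ±1`. When the critic itself is decoded from
neural reward signals it will be wrong some fraction of the time, and a
decoder that treats all feedback as trustworthy inherits the critic's
accuracy as a performance ceiling. The question studied here is whether a
per-trial *confidence* `ρ`, flagging how trustworthy the feedback is,
removes that ceiling.

## Actor

The actor (`init_actor()`, `actor_forward()`) is a fully connected
feed-forward network with one hidden layer of 5 binary processing elements
and one output node per action. Each node computes `P_j = tanh(Σ_i w_ij
x_i)` and emits the signed output `x_j = sgn(P_j)`; the output layer
consumes the hidden layer's *signed* outputs, consistent with a network of
binary nodes (a variant consuming the analog `P` is deliberately not
offered — it changes the consolidation geometry that the reward-penalty
rule relies on). The greedy policy picks the output node with the largest
activation. Conventions: `sgn(0) = +1`; greedy ties break toward the lowest
action index; no bias terms.

Weights start i.i.d. `Uniform(−0.1, 0.1)` — a naive decoder — and both the
weights and the input normalizer are re-initialized for every session.

### Input normalization

Because the decoder starts naive, inputs are scaled pseudo-real-time
(`normalize_input()`): each input is divided by the highest firing rate seen
on that input so far in the session, so every value lies in `[0, 1]` with no
pre-session calibration. The running maximum never decreases; inputs that
have never fired map to 0 through a floor guard rather than dividing by
zero. This makes the input statistics mildly non-stationary over the first
trials, which is part of the studied setting.

### Update rules

The plain Hebbian reward-penalty rule (`hrl_delta()`) updates every synapse
from its local pre/post activity and the global reward:

`Δw_ij = μ⁺ r (x_j − P_j) x_i + μ⁻ (1 − r)(1 − x_j − P_j) x_i`

At `r = 1` only the first term acts and vanishes as `P_j → x_j`
(consolidation: a rewarded, saturated node freezes). At `r = −1` both terms
act, so the rule is more sensitive to negative feedback. Both layers receive
the same global `(r, ρ)`; memory is one trial — no replay, no eligibility
traces.

The confidence-weighted rule (`hrl_delta_conf()`) inserts `ρ`:

`Δw_ij = μ⁺ ρ r (x_j − P_j) x_i + μ⁻ (1 − ρ r)(1 − x_j − P_j) x_i`

At `ρ = 1` this is exactly the plain rule. At `ρ = 0` the algebra leaves a
residual term `μ⁻ (1 − x_j − P_j) x_i`. Two readings are implemented:

* **`literal`** (default): the equation as written. Low-confidence trials
  still perturb the network through the residual term.
* **`gated`**: a hard gate — the full plain update when `ρ` exceeds 0.5,
  exactly zero otherwise.

The choice of default matters and was made on structural grounds. Under the
boolean-confidence protocol (below), a hard-gated actor at critic accuracy
`N` is an exact *trial-thinning* of the perfect-critic learner: it sees the
same distribution of correct updates, just fewer of them. Its expected
session error count is therefore bounded by roughly `1/N` times the
perfect-critic error count — at `N = 0.5`, no worse than twice. That makes
the gated rule nearly as good as a perfect critic on easy data, and it
erases the characteristic graded dependence of confidence-weighted
performance on critic accuracy that the method is known for. The literal
rule produces that graded dependence: its residual `ρ = 0` term injects
label-free perturbations whose rate equals the critic error rate, so
performance rises smoothly from well-above-chance (uninformative critic)
toward the common perfect-critic value. Both rules are exported and tested;
`confidence_rule = "gated"` reproduces the strict no-adaptation reading.

### Learning rates

The reward-penalty framework does not fix `μ⁺`, `μ⁻`. The defaults are
`μ⁺ = μ⁻ = 0.005`, calibrated once against a single operating point: with a
perfect critic, a naive decoder on noise-free synthetic sessions should
converge within the first dozen trials, putting mean session performance in
the mid-90s (%) for 100-trial sessions. Rates an order of magnitude larger
make single-trial jumps comparable to the whole initial weight scale
(`w0 = 0.1` times fan-in), which over-speeds convergence and inflates the
churn caused by wrong feedback; much smaller rates leave sessions
unconverged. With tanh nodes and `[0, 1]` inputs the effective step scales
with the number of co-active inputs, which is why appropriate per-synapse
rates look small.

## Critic

`critic_evaluate()` simulates a critic of accuracy `N`: ground truth is
`+1` iff the chosen action matches the label; with probability `N` the
critic reports the truth with `ρ = 1`, otherwise the negation with
`ρ = 0`. The actor never observes `N`, but in this protocol it knows
exactly *when* the feedback was trustworthy. Correctness is drawn i.i.d.
per trial by default; a quota mode (exactly `round(N·n)` correct trials per
session, shuffled) exists for single-session traces. Feedback correctness
is independent of the actor's weights given the chosen and correct actions.

This boolean-ρ protocol is an idealization: it cannot represent confidently
wrong feedback (mislabeled trials), only unconfident feedback. Estimating ρ
from data (e.g. distance to a decision boundary) is outside the package's
scope.

## Synthetic neural data

`generate_session()` produces two-state sessions from the Izhikevich model

`v' = 0.04 v² + 5 v + 140 − u + I`,  `u' = a (b v − u)`,

with after-spike reset `v ← c`, `u ← u + d` when `v` reaches +30 mV.
Excitatory parameters are heterogeneous: `a = 0.02`, `b = 0.2`,
`(c, d) = (−65, 8) + (15, −6)·e²`, `e ~ Uniform(0, 1)` per neuron, spanning
regular-spiking to chattering cells.

Three ensembles (default 20/20/20, the scale of a ~20-channel multi-unit
recording): one tuned to each state, one untuned. On each trial, neurons
tuned to the trial's state receive the on-stimulus (1) across the window;
all others receive 0; the untuned ensemble receives background drive only.
Synaptic current is `I = 10 × stimulus + Normal(0, 1)` per 0.5 ms step —
the gain drives sustained firing (~30 Hz) in tuned-on cells while the
background SD of 1 keeps off cells nearly silent, giving cleanly separable
noise-free classes. The firing-rate vector is the spike count over the 2 s
window (2000 ms; 4000 Euler steps at `dt = 0.5` ms); no smoothing —
normalization is the actor's job.

**Stimulus-noise perturbation.** To emulate degradation (electrode
deterioration, dropped units) without new model machinery, a configurable
fraction of neurons — tuned ones first — has its binary stimulus replaced,
step by step, by draws from `Normal(0.6, 0.2)` truncated at 0. This lowers
the stimulating current of tuned cells and blurs the class structure; the
overlap grows monotonically with the perturbed fraction, which
`class_overlap_diagnostic()` quantifies as the nearest-class-centroid error
rate in the plane of the first two principal components (≈0 separable,
≈0.5 indistinguishable). The centroid-error score is this package's
choice of a scalar diagnostic for what is otherwise judged by eye in PC
plots.

**What the generator does and does not emulate.** It produces rate-coded,
class-conditional multi-unit activity with biologically shaped spiking
statistics, heterogeneous cells, task-unrelated units, and a tunable
signal-to-noise axis. It does not couple neurons (no network synapses), has
no inhibitory population, no session-scale drift or electrode loss
mid-session, and its label schedule is balanced Bernoulli rather than a
behavioral sequence. Passing tests on this data therefore demonstrate
properties of the *update rules* under controlled difficulty, not decoder
performance on any particular real preparation; the external-session loader
(`load_external_session()`) exists so the same decoder can be run on real
binned recordings.

## Study design

`run_session()` runs the closed loop (normalize → forward → greedy action →
critic → update); performance is the percentage of trials whose action
matches the true label — ground truth, not the critic's report.
`run_study()` runs `n_sims` sessions per critic accuracy and mode, *paired*:
within a simulation, both modes share the same neural data, trial order,
actor initialization and feedback-correctness stream, so mode differences
are isolated from sampling noise, and at accuracy 1.0 the two modes coincide
exactly. Stability counts sessions that hold 100% correct over their last
50 (and last 30) trials; `paired_comparison()` applies the two-tailed paired
t-test at `α = 0.001` (the all-zero-difference case returns `t = 0, p = 1`;
a constant non-zero difference with zero variance is flagged as degenerate
rather than assigned an infinite statistic).

Because Izhikevich integration dominates runtime, the default is a *pooled*
data mode: one pool of 3× session-length trials is generated per study (per
noise level), and each session samples label-matched trials from it with
replacement. Fresh-session mode (`pooled = FALSE`) generates a new session
per simulation. All sub-seeds derive from one master seed, making every
result table bit-reproducible.

Problem sizes: the package's reference sweep (also what
`scripts/acceptance.R` runs) is 6 accuracies × 2 modes × 400 sessions × 100
trials on a 300-trial pool; the test suite uses 150 sessions per accuracy
for the same sweep and reduced layouts/windows (e.g. 6/6/4 ensembles,
400 ms windows) for property checks, sizes chosen to keep a full run in the
tens of seconds while holding Monte Carlo standard errors of cell means
near half a percentage point.

## Numerical choices and degenerate inputs

* Forward Euler at `dt = 0.5` ms, both state variables advanced from the
  pre-step state; the rest state `(v, u) = (−70, −14)` is an exact fixed
  point at `I = 0`, and every spike is immediately followed by `v = c`
  (both are tested invariants). Non-finite `v/u/I` aborts with the neuron
  and step named.
* `sgn(0) = +1`; greedy ties go to action 1; the normalizer floor is
  `1e-12`, and never-active inputs normalize to 0.
* The perturbing Gaussian is truncated at 0 (stimulus is a drive, not a
  sign-reversing input).
* Sessions reject negative rates, labels outside {1, 2}, and fewer than
  two classes; the overlap diagnostic rejects all-zero-variance data and
  classes with fewer than 2 trials; stability windows longer than the
  session are errors, not zeros.
* Config files are flat YAML with unknown-key rejection; every output
  carries the resolved config, master seed and a deterministic 64-bit
  FNV-1a config hash.

## Known limitations

* The boolean confidence protocol credits the critic with knowing when it
  is wrong; real confidence estimates are graded and imperfect, and the
  literal rule's behavior under graded `ρ ∈ (0, 1)` is implemented but not
  characterized here.
* One-trial memory and a two-action greedy policy: no temporal credit
  assignment, no exploration schedule, no multi-target tasks.
* The pooled-data mode reuses trials across sessions within a study; it
  matches fresh-session statistics closely on this generator but is not
  identical, and fresh mode should be used when trial-level independence
  across simulations matters.
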