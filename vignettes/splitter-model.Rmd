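---
title: "A closed-loop model of task-dependent splitter cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A closed-loop model of task-dependent splitter cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Hippocampal "splitter" cells fire at a given track location only in a given
task context — here, only after one of two visual cues (A or B) shown at the
start of a Y-maze trial. In a cue-dependent task (cue A rewards port D, cue B
rewards port E), location alone is an insufficient state: the optimal action
at the choice point depends on a cue seen tens of timesteps earlier, so the
task is non-Markovian in position. `splithpc` simulates a closed-loop model
in which a hippocampal (HPC) network and a reinforcement-learning agent
co-evolve: plateau-gated three-factor plasticity builds cue-conditional
("split") state representations exactly when — and only when — they improve
the agent's reward, while the agent's behavior supplies the reward
correlations that the plasticity needs.

## Model

**Environment.** The agent runs at unit velocity along a 100-position track
(`x = t`): a cue zone `[0, 20)` where one of two cues is shown, a central
stem `[20, 60)` (segment C), and two reward branches `[60, 100)` (D and E)
entered by a binary turn at `t_choice = 60`. External input is a bank of 120
Gaussian positional tuning curves `u_k(x) = exp(-((x - x_k)/sigma)^2)`
(`sigma = 5`), gated by role: the cue-zone channels are split into an
A-dedicated (even ids) and B-dedicated (odd ids) half and are driven only
while their cue's trial is in the cue zone; stem channels are purely
positional; branch channels are dedicated to the visited branch; 20 reserve
channels stay dormant (they become the novel input lines of the remapping
experiment). Channel id, tuning centre and matching neuron id coincide, so
the frozen identity input matrix `M` gives each neuron a place field at its
own index.

**Three-compartment HPC neurons.** Each of the 120 neurons has a basal
compartment `b = M u`, an apical compartment driven by recurrent feedback,
and a soma

```
s_i = (1 - beta_i) b_i + beta_i * b_i * gamma_a(a_i)
beta_i = gamma_beta( sum_j W_ij ),   gamma_f(x) = (tanh(m_f (x - c_f)) + 1)/2
```

`beta` is the degree to which the soma "listens" to its apical dendrite: a
saturating function of the total incoming recurrent weight, recomputed only
at trial boundaries (weights update in batch at the end of each trial). With
`W = 0`, `beta ~ 8e-7` and the soma is a pure basal readout — before
learning, somatic activity carries no cue memory beyond the cue zone, which
the test suite asserts exactly.

**Plasticity.** Somatic activity leaves eligibility traces
(`tau_e = 10` for the recurrent rule, `tau_ea = 20` for the action rule).
A fixed induction protocol injects one plateau per neuron per matching
trial: even neurons on A trials, odd neurons on B trials, each at its
plateau time `t_plateau[i] = i`. The plateau acts as a pass filter `phi`:
only plateau-tagged somatic activity enters the within-trial "proto-weight"
accumulator, which converts into a weight change once reward `r` (1
delivered / 0 omitted) arrives:

```
dW_ij = eta_W (r - r0) * integral( phi[s_i] e_j dt ) - lambda_w W_ij
```

with `r0 = 0.5`, clipping to `[0, W_max = 0.15]` after the update. At
baseline reward the update is pure multiplicative decay; rewarded trials
potentiate plateau-tagged pairs, omissions depress them.

**Action network.** Two mutually inhibiting action neurons (left/D,
right/E) integrate the somatic population through state-action weights `Q`
(bounds ±0.15), with per-step Gaussian noise (`sd 0.75`). The turn is
`argmax(v + policy noise)` (`sd 5`) at `t_choice`, replaced by a fair coin
on 10 % of trials; the winner is clamped to 1 for ten steps. `Q` learns by
the analogous three-factor rule with baseline `r_q = 0.6` and no decay:
because `r_q` exceeds the chance reward rate, at-chance policies are on
average depressed, and only representations supporting above-baseline
reward latch.

## Numerical choices the model equations leave open

These were fixed by dimensional/scale analysis of the reference parameter
set, then verified against the headline dynamics; each is a configuration
option of `sim_params()`, with the adopted reading as the default.

* **Integrator gain.** The dynamic variables (`a`, `v`, both `e`) are
  integrated as `x <- x (1 - dt/tau) + dt * drive`, whose fixed point under
  constant drive is `tau * drive`. Under the alternative gain-1 reading the
  apical drive could never exceed `W_max * sum(s) ~ 1.3`, far below the gate
  offset `c_a = 5`, so the apical gate could never open and no splitter
  could form; likewise trained action activities would be an order of
  magnitude below the policy noise. Under the adopted reading, `c_a = 5`
  corresponds to roughly one saturated recurrent synapse driving the apical
  compartment — a sensible gating threshold.
* **Plateau window** (`plateau_halfwidth`, default ±10 steps around
  `t_plateau`). With a single-step window the attainable recurrent row sum
  (~0.5 at a perfect policy) never reaches the modulation offset
  `c_beta = 1.4`, so splitting would be impossible at the reference learning
  and decay rates; a window covering the neuron's activity bump recovers the
  full three-factor integral while keeping plateau time meaningful for the
  plastic-input experiments.
* **Action credit window** (`action_credit_window = "choice"`). The
  activity–eligibility products of the `Q` rule are accumulated during the
  ten post-choice clamp steps: credit is evaluated at the commitment event,
  mirroring the plateau gating of the recurrent rule. Accumulating the whole
  trial instead makes single-trial updates (`eta_Q (r - r_q) proto`) larger
  than the entire `Q` range, which rail-slams the weights and prevents any
  policy learning.
* **Winner-take-all competition** (`inhibition_timescale = "step"`). The
  fixed inhibition (±0.125 off-diagonal) applied at full strength each step
  makes the difference between the two action units an unstable competition
  mode, so small accumulated asymmetries are amplified toward the choice
  point. The stable alternative (inhibition on the `tau_v` timescale) yields
  a short evidence window; in that regime the co-evolution loop never
  bootstraps (behavior stays at chance and no splitters latch), because the
  first splitters emerge near the cue zone, outside a short window's reach.
* **Action units are linear** (`rectify_v = FALSE`, `credit_rectify =
  FALSE`): negative activity both expresses and (with the raw signed credit)
  actively unlearns the suppressed action. Rectified variants trap the
  policy in an inexpressive state once the state-action weights drift to
  their floor at chance reward.
* **Noise notation.** The reference values `N(0, 0.75)` and `N(0, 5)` are
  read as (mean, sd); both the sd and the variance reading reproduce the
  headline dynamics, and the choice is exposed via `sigma_v` / `sigma_p`.
* **Update order.** Within a step: apical (from the previous step's soma),
  then basal, soma, eligibilities, plateau accumulation, action step. All
  clipping is applied after the full update. The decay `-lambda_w W` applies
  on every trial. Self-connections are permitted (`allow_self`).
* **Geometry.** Segment boundaries are under-determined (the neuron-index
  convention of the population analyses and the choice time imply slightly
  different stem extents); the defaults `[0,20)/[20,60)/[60,100)` are one
  consistent reading and are configuration, not hard-coded.

## What the simulations reproduce

With the default (reference) parameters, seeds 1–5 of
`preset("cue_dependent_main")`:

* behavior and splitness co-evolve from chance, with stem splitters
  appearing stochastically, then latching; the majority of the 40 stem
  neurons pass the split criterion by trial ~500 in most seeds;
* split onsets order along the stem ("zipper", Spearman onset~position
  rho ≈ 0.9);
* final per-cue performance 0.91–0.98 against the ceiling
  `1 - p_rand/2 = 0.95`;
* the identical induction protocol under random reward produces zero
  splitters and a steady-state reward of 0.5;
* forcing behavior to chance mid-run collapses mean |splitness| from ~0.9
  to ~0.000 (representation re-merges);
* held-out neurons (80/81) released into a trained network reach the split
  criterion 1–6 trials after release (median ≈ 4), versus hundreds of
  trials during de-novo learning.

The split criterion is `|splitness| > split_threshold (0.5) x` the neuron's
peak windowed in-field rate, persisting `split_persist (50)` evaluable
trials, on a trailing 100-trial window; no canonical value exists for either
knob, so both are exposed and reported. For few-shot
latencies a 10-trial window (persistence 5) is used — a 100-trial running
mean cannot resolve single-trial timescales. In-field position is the
plateau position. Running means are trailing (uncentered), the conservative
choice for online series.

## Problem sizes used by the tests

Unit tests run on a 16-position maze with the same segment proportions.
The acceptance checks run the full 120-neuron model: holdout runs are
stopped at trial 900 (150 trials after release, ample for a ≤ 10-trial
criterion), the random-reward and prune runs use the full 4,000 /
scaled 3,000 trials, the behavior-reset and ablation runs scale the
perturbation to trial 1,200–1,500 of 2,200–3,000 trials (all still past
behavioral asymptote, which occurs by ~trial 700).

## What the synthetic environment does and does not emulate

The generator reproduces the study conditions exactly: 1-D unit-velocity
locomotion, two cues, deterministic or Bernoulli(0.5) reward, i.i.d. fair
cue draws, externally scheduled plateaus. It does not emulate 2-D
locomotion, velocity or head-direction modulation, biophysical plateau
generation, spiking, or trial-to-trial sensory variability; passing tests
therefore demonstrate properties of the model class, not of biological
recordings.

## Known limitations

* **A sensory shortcut survives the pruning perturbation.** The cue-zone
  input channels are cue-dedicated by construction, and the winner-take-all
  action dynamics amplify accumulated drive across the delay period. Once
  the cue-zone state-action weights saturate (they are potentiated on every
  rewarded matched trial and nothing in the learning rules depresses
  them), the agent retains a direct cue-to-turn pathway that does not pass
  through the learned recurrent representation. Consequently, pruning the
  B-splitters' recurrent weights leaves B-trial behavior largely intact in
  this implementation (~0.9 instead of the expected collapse to ~0.5), and
  splitter ablations produce only small deficits. Action-dynamics variants
  that close this shortcut (rectified units, stable competition) were
  explored systematically and fail to bootstrap learning at all; the
  corresponding acceptance checks are left failing rather than weakened.
  The shortcut does not affect the representational results: splitness,
  zipper ordering, task-dependence, re-merging under behavioral reset and
  few-shot holdout integration are all properties of the recurrent weights,
  which behave as described.
* **The plastic-input variant is behaviorally unstable.** With learnable
  input weights (`novel_cue_port` preset), `M` correctly remaps onto novel
  input channels by plateau/input coactivation, but only a per-entry
  bound (`M_max = 0.75`) constrains them: learned rows sum well above 1, basal
  activity inflates several-fold, and the inflated credit scale keeps
  behavior at chance. The remapping claims are tested structurally; the
  behavioral claims of that supplementary experiment are not asserted.
* Trial-level batch updates make within-trial dynamics deterministic given
  the cue, turn and noise; no within-trial plasticity is modeled.

## A worked example

```{r, eval = FALSE}
library(splithpc)
x <- run_experiment(preset("cue_dependent_main"), seed = 1)
summary(x)
plot(x)                         # performance, splitness, population zipper
head(split_onset_times(x, neurons = stem_neurons(x$params)))
```

Scaled-down runs (`preset("cue_dependent_main", n_trials = 200)`) honor all
other defaults and are convenient for exploration.
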