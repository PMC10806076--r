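# splithpc

A closed-loop simulation of how hippocampal "splitter" cells and behavior
co-evolve while an agent learns a cue-dependent Y-maze task.

Splitter cells fire at a given place only in a given task context — here,
only after one of two visual cues (A or B) shown at the start of the track.
In the cue-dependent task (cue A rewards port D, cue B rewards port E) the
optimal turn depends on a cue seen long before the choice point, so place
alone is an insufficient state. The package implements a three-stage model
that learns such tasks from scratch:

1. **Environment** — a 1-D Y-maze traversed at unit velocity (`x = t`),
   with Gaussian positional tuning curves `u_k(x) = exp(-((x - x_k)/σ)²)`
   as external input; cue-zone channels are cue-dedicated, branch channels
   are port-dedicated.
2. **HPC network** — 120 three-compartment rate neurons. Somatic activity
   combines basal (external) input with apical (recurrent) feedback,
   `s = (1-β) b + β b γ_a(a)`, where `β = γ_β(Σ_j W_ij)` gates how much the
   soma listens to its apical dendrite. Recurrent weights learn by a
   plateau-gated, reward-modulated three-factor rule over presynaptic
   eligibility traces (behavioral-timescale synaptic plasticity):
   `ΔW_ij = η_W (r - r₀) ∫ φ[s_i] e_j dt - λ_w W_ij`, updated in batch at
   trial end, with externally scheduled plateaus (even-id neurons on A
   trials, odd-id on B trials, at `t_plateau[i] = i`).
3. **Action network** — two mutually inhibiting (winner-take-all) action
   neurons read out the population through state-action weights `Q`,
   learned by the analogous rule `ΔQ_li = η_Q (r - r_q) ∫ v_l e_i dt`;
   the turn is `argmax(v + policy noise)`, with a 10 % random-turn
   exploration floor.

All parameters default to the model's reference values (see
`?sim_params`). The shipped experiment presets reproduce the study designs:
`cue_dependent_main`, `random_reward_main`, `behavior_reset`, `prune_B`,
`ablate_general`, `ablate_specific`, `holdout_fewshot`, `novel_cue_port`.

## A worked example

```r
library(splithpc)
x <- run_experiment(preset("cue_dependent_main"), seed = 1)
summary(x)
```

```
Experiment 'cue_dependent_main' (cue_dependent), 4000 trials, seed 1
  final 500 trials: 91.8% correct (A: 92.4%, B: 91.2%), mean reward 0.918
  split stem neurons: 40 / 40 (median onset trial 303.5)
  zipper (Spearman onset ~ position): rho = 0.95
```

The agent starts with a naive (chance) policy; stem neurons are pure place
cells. Over ~300–500 trials cue-conditional splitters emerge in a "zipper"
from the cue end of the stem toward the reward end (the positive Spearman
correlation between split-onset trial and field position), and per-cue
performance approaches the exploration-limited ceiling `1 - p_rand/2 =
0.95`. The same induction protocol under `random_reward_main` produces zero
splitters and a mean reward of 0.5 — splitting is integrated only when the
task structure makes it useful.

```r
plot(x)                                        # performance / splitness / zipper panels
splitness(x, neuron = 40)                      # A-vs-B in-field rate difference
split_onset_times(x, neurons = stem_neurons(x$params))
rate_map(run_experiment(preset("holdout_fewshot"), seed = 1), 80,
         align_trial = 750)                    # held-out neuron around release
coef(x)$W                                      # final recurrent weights
```

A command-line front end with `simulate` / `analyze` / `report` /
`selftest` verbs is installed at
`system.file("cli", "splithpc.R", package = "splithpc")`; runs are written
as a directory of delimited text logs plus a serialized state that supports
bit-exact resuming (`save_log()` / `load_log()`).

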