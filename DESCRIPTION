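Package: splithpc
Title: Closed-Loop Hippocampal Network Model of Task-Dependent Splitter Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a closed-loop model of hippocampal representation
    learning in a Y-maze. Three-compartment rate neurons (basal, apical,
    soma) receive positional tuning-curve input and recurrent apical
    feedback gated by a weight-dependent modulation factor; recurrent
    weights are learned with a plateau-gated, reward-modulated three-factor
    rule with presynaptic eligibility traces (behavioral-timescale synaptic
    plasticity), while a two-unit winner-take-all action network learns
    state-action weights from the same reward signal. The package ships the
    cue-dependent and random-reward task presets, perturbation experiments
    (behavior reset, splitter pruning, general and cue-specific ablation,
    held-out neuron few-shot induction, novel cue and reward-port
    remapping), and analysis of splitness, split-onset ordering, behavioral
    performance and rate maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
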