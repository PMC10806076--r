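name: ablate_general
task:
  variant: cue_dependent
n_trials: 4000
perturbations:
  - kind: ablate_general
    trial: 2000
    fraction: 0.5
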