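name: prune_B
task:
  variant: cue_dependent
n_trials: 4000
perturbations:
  - kind: prune_B_splitters
    trial: 2000
    freeze: true
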