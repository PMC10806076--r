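name: novel_cue_port
task:
  variant: cue_dependent
n_trials: 4000
input_plasticity: true
perturbations:
  - kind: novel_cue_and_port
    trial: 2000
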