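name: cue_dependent_main
task:
  variant: cue_dependent
n_trials: 4000
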