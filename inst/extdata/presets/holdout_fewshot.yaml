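name: holdout_fewshot
task:
  variant: cue_dependent
n_trials: 4000
holdouts: [80, 81]
release_trial: 750
trace_neurons: [80, 81]
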