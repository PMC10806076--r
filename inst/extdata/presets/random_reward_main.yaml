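name: random_reward_main
task:
  variant: random_reward
n_trials: 4000
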