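# Example experiment configuration: override any subset of the defaults
# returned by default_config().  Unknown keys are rejected by name.
scheme: default
n_lateral: 2
seed: 7
protocol:
  trials: 8
  conc: 1.0
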