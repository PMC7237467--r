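# Calibrated hyperparameter profile (output of the calibrate_model() grid
# harness; overrides over agent_params() defaults). The study's own fitted
# values are unpublished; these reproduce the model-level group statistics.
thompson:
  gain: 12
  beta3: 0.1
  beta2: 0.01
  beta1: 1.0
bayes:
  gain: 8
  beta3: 0.1
  beta2: 0.01
  beta1: 1.0
rl:
  alpha: 0.0085
  gamma: 0.3
  lambda: 0.8
  gain: 10
  beta3: 0.1
  beta2: 0.01
  beta1: 1.0
ann:
  alpha: 0.0005
  gain: 2
  beta3: 0.1
  beta2: 0.01
  beta1: 1.0
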