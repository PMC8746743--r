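# Example run configuration: two-level incentive design, four simulated
# subjects sharing the default reward-rate-optimal profile.
study: 1
n_subjects: 4
seed: 1
ndt: 0.4
cost:
  form: quadratic
  weight: 1.0
  threshold_weight: 0.0
congruence_offsets:
  drift: -0.3
  threshold: 0.1
interval_end: discard
pool_subjects: true
min_trials: 100
recovery:
  regime: fitted
  n_trials: 2000
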