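# Default desk-scale run: full cohort (200 athletes, 24 bi-weekly points),
# shrunken model profile, 1000 bootstrap draws.
cohort:
  n_per_group: {high_carb: 68, high_protein: 65, balanced: 67}
  n_timepoints: 24
  lag_steps: 3
  missing_rate: 0.05
  outlier_rate: 0.01
  seed: 1
preprocess:
  mice_iterations: 5
split:
  train_frac: 0.8
  n_folds: 5
  gap_steps: 4
  window: 3
model:
  profile: desk
  outcome: fatigue
  mcid: 1.0
analysis:
  max_lag: 6
  n_boot: 1000
  shap_athletes: 40
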