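# Full-size profile: printed hyperparameters (embedding 128, LSTM 128,
# bidirectional 128 per direction, final 64; 500 estimators, depth 6;
# 5000 bootstrap draws). Substantially slower than desk_scale.
cohort:
  n_per_group: {high_carb: 68, high_protein: 65, balanced: 67}
  n_timepoints: 24
  lag_steps: 3
  missing_rate: 0.05
  outlier_rate: 0.01
  seed: 1
preprocess:
  mice_iterations: 10
split:
  train_frac: 0.8
  n_folds: 5
  gap_steps: 4
  window: 3
model:
  profile: paper
  outcome: fatigue
  mcid: 1.0
analysis:
  max_lag: 6
  n_boot: 5000
  shap_athletes: 200
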