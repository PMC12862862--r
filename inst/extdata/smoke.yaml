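# Minimal smoke-test scenario: tiny cohort, shrunken model.
cohort:
  n_per_group: {high_carb: 12, high_protein: 12, balanced: 12}
  n_timepoints: 16
  lag_steps: 3
  missing_rate: 0.03
  outlier_rate: 0.01
  seed: 1
preprocess:
  mice_iterations: 3
split:
  n_folds: 3
  gap_steps: 4
  window: 2
model:
  profile: desk
  outcome: fatigue
  temporal: {embed_dim: 8, lstm_units: 8, bilstm_units: 8, final_units: 4,
             max_epochs: 8, early_stop_patience: 8}
  boost: {n_estimators: 30}
analysis:
  max_lag: 5
  n_boot: 200
  shap_athletes: 6
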