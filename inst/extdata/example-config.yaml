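# Example jitterhrv pipeline configuration (reduced scale).
# Any key omitted falls back to the package default; unknown keys error.
seed: 1
cohort:
  n_participants: 5
  duration_mean_h: 8.43
  duration_sd_h: 0.5
  stage_props: {W: 0.300, S1: 0.026, S2: 0.411, S3: 0.116, R: 0.147}
  mean_dwell_epochs: {W: 7, S1: 6, S2: 10, S3: 7, R: 8}
ladder:
  n_levels: 10
  target_mae_ms: 60
evaluate:
  levels: [0, 2, 4, 6, 8, 10]
  k_folds: 10
  knn_k: 10
  schemes: [micro, macro]
  feature_subsets: [all]
beat_pairs:
  n_participants: 27
  beats_per: 100
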