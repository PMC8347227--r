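# Example pipeline configuration for the bcitransfer CLI.
# Desk-scale settings; see the methods vignette for the rationale.
seed: 1
output_dir: out

cohort:
  M: 6
  trials_per_class: 40
  C: 16
  fs: 128
  trial_s: 6
  noise: 4

features:
  grid_w: 16
  grid_h: 16
  window_s: 2
  step_s: 1
  interval_start: 0
  interval_end: 6
  n_csp: 6
  morlet_param: 32

training:
  epochs: 50
  p_prime: 100
  learning_rate: 0.001
  l1: 0.0005
  l2: 0.0005
  finetune_epochs: 20

kernel:
  g_prime: 50
  representation: fused
  kpca_components: 20

transfer:
  strategies: [single, multi]
  n_sources: 4
  v_source: cv
  cv_folds: 2
  test_fraction: 0.1
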