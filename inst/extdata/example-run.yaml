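# Example run configuration for `exec/mindwandr run --config ...` or
# read_run_config(). Omitted keys keep the package defaults (the full
# 14-subject oddball design).
seed: 42
mode: both
normalization: per_subject
k_folds: 5
ablate: false
stats: true
generator:
  n_subjects: 14
  n_blocks: 25
  tone_mode: exact
  mw_attenuation: 0.3
  artifact_probability: 0.05
  render: preprobe
balance:
  k_neighbors: 5
  min_minority_per_subject: 5
model:
  family: svm
  cost: 1.0
  gamma: scale
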