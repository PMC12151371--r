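# Demo pipeline configuration: simulate a small cohort, label it, and
# evaluate the fusion model against logistic regression on the daily task.
seed: 20
task: daily
cv_folds: 5
models: [fusion, logistic_regression]
fusion:
  max_epochs: 30
synthetic:
  n_subjects: 20
  n_days: 120
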