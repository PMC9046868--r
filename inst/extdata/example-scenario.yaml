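# Example scenario: adaptive BRAF/MEK inhibition at reduced resolution.
# Any key omitted here falls back to the packaged reference defaults;
# unknown keys are rejected at load time.
grid:
  n_spatial: 16
  n_structural: 16
treatment:
  mode: adaptive
  drug_order: BRAF_MEKi
  lower_threshold: 0.25
  upper_threshold: 0.5
  decision_interval: 1
run:
  horizon: 120
  snapshot_interval: 10
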