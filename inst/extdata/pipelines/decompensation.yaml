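# Trend pattern: systolic BP relative change over a trailing 15-minute
# window, stepped every 5 minutes; a drop of more than 20% raises the
# alarm. The raw drop indicator is additionally evaluated against the
# patient's own running baseline (z-score states).
channels:
  SBP: scalar
rules:
  baseline_z:
    mode: dynamic_z
    z_warn: 2
    z_path: 3
    min_n_eff: 20
patterns:
  - id: bp15
    category: trend_delta
    inputs: [SBP]
    params:
      mode: relative_change
      window_ms: 900000
      step_ms: 300000
      threshold: -0.20
      direction: below
    output: sbp_drop15
evaluate:
  sbp_drop15: baseline_z
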