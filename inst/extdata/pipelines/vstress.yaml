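# Illustrative composite "stress level" feature: heart-rate-variability
# statistics extracted from the R-R interval series are combined with a
# galvanic skin response channel and fed to a pluggable predictor
# ("vstress_model" must be supplied to run_pipeline() via `models=` or as
# an artifact directory path). No accuracy claims attach to this example.
channels:
  RR_int: time_series
  GSR: scalar
patterns:
  - id: hrv
    category: signal_features
    inputs: [RR_int]
    params:
      features: [sdnn, rmssd]
      window_ms: 300000
    output: hrv
  - id: stress
    category: ml_inference
    inputs: [hrv.sdnn, hrv.rmssd, GSR]
    params:
      model: vstress_model
      window_ms: 300000
    output: v_stress
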