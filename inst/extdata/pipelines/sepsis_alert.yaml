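# Classic threshold-logic pattern: fever plus tachycardia within a
# 5-minute synchronization tolerance raises a boolean sepsis alert.
channels:
  Temp: scalar
  HR: scalar
patterns:
  - id: sepsis
    category: scalar_logic
    inputs: [Temp, HR]
    params:
      rule: "Temp > 38 AND HR > 100"
      tolerance_ms: 300000
    output: sepsis_alert
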