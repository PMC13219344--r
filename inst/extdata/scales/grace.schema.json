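{
  "scale_id": "grace",
  "stub": true,
  "note": "Schema stub, not a loadable scale. The GRACE ACS risk score mixes banded points with continuous coefficients (age, heart rate, systolic BP, creatinine), so a faithful fixture needs the full published coefficient tables plus a continuous-coefficient extension of the sum-of-points schema. Supply a complete fixture with the structure below to enable it.",
  "expected_schema": {
    "scale_id": "string",
    "components": "[{name, levels: {label: points}}] -- banded factors (Killip class, cardiac arrest, ST deviation, elevated enzymes)",
    "continuous_components": "[{name, breaks: [..], points: [..]}] -- piecewise-linear age/HR/SBP/creatinine contributions (extension; not consumed by load_scale())",
    "bands": "[{lo, hi, label}] -- risk categories over the total"
  }
}
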