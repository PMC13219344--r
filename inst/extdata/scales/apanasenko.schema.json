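{
  "scale_id": "apanasenko",
  "stub": true,
  "note": "Schema stub, not a loadable scale. The Apanasenko somatic-health express assessment bands anthropometric and functional indices (vital capacity/weight, grip strength/weight, HR x SBP / 100, recovery time after exercise, weight/height) into points summed to a five-level health rating. The published banding tables are sex-specific; supply complete fixtures (one per sex) with the structure below to enable it.",
  "expected_schema": {
    "scale_id": "string",
    "components": "[{name, levels: {label: points}}] -- one component per banded index",
    "bands": "[{lo, hi, label}] -- low / below-average / average / above-average / high"
  }
}
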