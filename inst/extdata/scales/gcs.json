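{
  "scale_id": "gcs",
  "description": "Glasgow Coma Scale: sum of eye, verbal and motor responses (3-15).",
  "components": [
    {
      "name": "eye",
      "levels": {
        "none": 1,
        "to_pressure": 2,
        "to_sound": 3,
        "spontaneous": 4
      }
    },
    {
      "name": "verbal",
      "levels": {
        "none": 1,
        "sounds": 2,
        "words": 3,
        "confused": 4,
        "oriented": 5
      }
    },
    {
      "name": "motor",
      "levels": {
        "none": 1,
        "extension": 2,
        "abnormal_flexion": 3,
        "normal_flexion": 4,
        "localising": 5,
        "obeys_commands": 6
      }
    }
  ],
  "bands": [
    { "lo": 3, "hi": 8, "label": "severe" },
    { "lo": 9, "hi": 12, "label": "moderate" },
    { "lo": 13, "hi": 15, "label": "mild" }
  ]
}
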