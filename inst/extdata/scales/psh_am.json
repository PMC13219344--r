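{
  "scale_id": "psh_am",
  "description": "PSH Assessment Measure (2014 consensus structure): Clinical Feature Scale (six features graded 0-3) plus Diagnosis Likelihood Tool (eleven yes/no features, 1 point each); total = CFS + DLT, banded into unlikely / possible / probable PSH.",
  "components": [
    {
      "name": "cfs_heart_rate",
      "levels": { "under_100": 0, "100_to_119": 1, "120_to_139": 2, "140_or_more": 3 }
    },
    {
      "name": "cfs_respiratory_rate",
      "levels": { "under_18": 0, "18_to_23": 1, "24_to_29": 2, "30_or_more": 3 }
    },
    {
      "name": "cfs_systolic_bp",
      "levels": { "under_140": 0, "140_to_159": 1, "160_to_179": 2, "180_or_more": 3 }
    },
    {
      "name": "cfs_temperature",
      "levels": { "under_37": 0, "37_to_37_9": 1, "38_to_38_9": 2, "39_or_more": 3 }
    },
    {
      "name": "cfs_sweating",
      "levels": { "nil": 0, "mild": 1, "moderate": 2, "severe": 3 }
    },
    {
      "name": "cfs_posturing",
      "levels": { "nil": 0, "mild": 1, "moderate": 2, "severe": 3 }
    },
    {
      "name": "dlt_simultaneous_features",
      "levels": { "no": 0, "yes": 1 }
    },
    {
      "name": "dlt_paroxysmal_episodes",
      "levels": { "no": 0, "yes": 1 }
    },
    {
      "name": "dlt_overreactivity_to_stimuli",
      "levels": { "no": 0, "yes": 1 }
    },
    {
      "name": "dlt_persist_3_days",
      "levels": { "no": 0, "yes": 1 }
    },
    {
      "name": "dlt_persist_2_weeks_post_injury",
      "levels": { "no": 0, "yes": 1 }
    },
    {
      "name": "dlt_persist_despite_treatment",
      "levels": { "no": 0, "yes": 1 }
    },
    {
      "name": "dlt_medication_for_sympathetic_features",
      "levels": { "no": 0, "yes": 1 }
    },
    {
      "name": "dlt_two_or_more_episodes_daily",
      "levels": { "no": 0, "yes": 1 }
    },
    {
      "name": "dlt_no_parasympathetic_features",
      "levels": { "no": 0, "yes": 1 }
    },
    {
      "name": "dlt_no_other_cause",
      "levels": { "no": 0, "yes": 1 }
    },
    {
      "name": "dlt_antecedent_brain_injury",
      "levels": { "no": 0, "yes": 1 }
    }
  ],
  "bands": [
    { "lo": 0, "hi": 7, "label": "psh_unlikely" },
    { "lo": 8, "hi": 16, "label": "psh_possible" },
    { "lo": 17, "hi": 29, "label": "psh_probable" }
  ]
}
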