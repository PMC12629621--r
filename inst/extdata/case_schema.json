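{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "psarag case record",
  "type": "object",
  "required": ["case_id", "age"],
  "additionalProperties": false,
  "properties": {
    "case_id": {"type": "string", "minLength": 1},
    "age": {"type": "integer", "minimum": 18, "maximum": 120},
    "comorbidities": {
      "type": "array",
      "items": {"enum": [
        "myocardial_infarction", "congestive_heart_failure",
        "peripheral_vascular_disease", "cerebrovascular_disease", "dementia",
        "chronic_pulmonary_disease", "rheumatic_disease",
        "peptic_ulcer_disease", "mild_liver_disease",
        "diabetes_uncomplicated", "diabetes_with_complications", "hemiplegia",
        "renal_disease", "any_malignancy", "leukemia", "lymphoma",
        "moderate_severe_liver_disease", "metastatic_solid_tumor", "aids",
        "none"]}
    },
    "luts": {"type": "boolean"},
    "hematuria": {"type": "boolean"},
    "active_uti": {"type": "boolean"},
    "dre": {"enum": ["not_done", "normal", "abnormal"]},
    "psa_history": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["value", "months_ago"],
        "properties": {
          "value": {"type": "number", "minimum": 0},
          "months_ago": {"type": "integer", "minimum": 0},
          "context": {"enum": ["screening", "follow_up", "symptomatic"]}
        }
      }
    },
    "risk_factors": {
      "type": "array",
      "items": {"enum": ["family_history_prostate_ca", "brca_carrier",
                         "african_ancestry"]}
    },
    "preference": {"enum": ["requests_screening", "declines", "unstated"]},
    "free_text": {"type": "string"},
    "category": {"enum": ["cat1_screen_recommended",
                          "cat2_screen_not_recommended",
                          "cat3_normal_followup", "cat4_elevated_psa",
                          "cat5_other"]}
  }
}
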