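{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "StudyRecord list",
  "description": "Array of structured study-outcome records consumed by the scoring engine. Durations are months; rates are on the 0-100 scale as printed; 'not reached' durations are encoded as the string token \"not reached\". The flat CSV schema uses the same field names with os_/pfs_ prefixes for the nested endpoints.",
  "type": "array",
  "items": { "$ref": "#/$defs/study_record" },
  "$defs": {
    "ternary": { "enum": ["yes", "no", "unknown"] },
    "duration": {
      "oneOf": [
        { "type": "number", "minimum": 0 },
        { "const": "not reached" }
      ]
    },
    "hr_estimate": {
      "type": "object",
      "required": ["point", "lower95", "upper95"],
      "properties": {
        "point": { "type": "number", "exclusiveMinimum": 0 },
        "lower95": { "type": "number", "exclusiveMinimum": 0 },
        "upper95": { "type": "number", "exclusiveMinimum": 0 }
      }
    },
    "survival_endpoint": {
      "type": "object",
      "properties": {
        "endpoint_kind": { "enum": ["OS", "PFS"] },
        "gain_months": { "type": "number" },
        "control_median_months": { "type": "number", "exclusiveMinimum": 0 },
        "hr": { "$ref": "#/$defs/hr_estimate" },
        "landmark_gain_pct": { "type": "number" },
        "landmark_years": { "type": "integer" }
      },
      "dependentRequired": { "landmark_gain_pct": ["landmark_years"] }
    },
    "response_summary": {
      "type": "object",
      "properties": {
        "orr_pct": { "type": "number", "minimum": 0, "maximum": 100 },
        "dcr_pct": { "type": "number", "minimum": 0, "maximum": 100 },
        "dor_months": { "$ref": "#/$defs/duration" },
        "dor_statistic": { "enum": ["mean", "median", "unspecified"] },
        "docb_months": { "$ref": "#/$defs/duration" },
        "response_criteria": { "type": "string" }
      }
    },
    "adjustment_flags": {
      "type": "object",
      "properties": {
        "toxicity_ge30pct_grade34": { "$ref": "#/$defs/ternary" },
        "toxicity_reduced_vs_control": { "$ref": "#/$defs/ternary" },
        "qol_assessed": { "$ref": "#/$defs/ternary" },
        "qol_improved": { "$ref": "#/$defs/ternary" },
        "phase4_confirmation": { "$ref": "#/$defs/ternary" },
        "crossover_penalty": { "$ref": "#/$defs/ternary" }
      }
    },
    "study_record": {
      "type": "object",
      "required": ["record_id", "design"],
      "properties": {
        "record_id": { "type": "string", "minLength": 1 },
        "design": {
          "enum": ["comparative_superiority", "comparative_noninferiority",
                   "single_arm", "patient_n_of_1"]
        },
        "primary_endpoint": { "enum": ["OS", "PFS", "ORR", "other", "safety"] },
        "n_subjects": { "type": "integer", "exclusiveMinimum": 0 },
        "superiority_met": { "$ref": "#/$defs/ternary" },
        "noninferiority_met": { "$ref": "#/$defs/ternary" },
        "os": { "$ref": "#/$defs/survival_endpoint" },
        "pfs": { "$ref": "#/$defs/survival_endpoint" },
        "single_arm_pfs_months": { "type": "number", "minimum": 0 },
        "response": { "$ref": "#/$defs/response_summary" },
        "best_response": { "enum": ["CR", "PR", "MR", "SD", "PD"] },
        "flags": { "$ref": "#/$defs/adjustment_flags" },
        "subgroup_label": { "type": "string" },
        "entity": { "type": "string" },
        "therapy_class": { "type": "string" },
        "note": { "type": "string" }
      }
    }
  }
}
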