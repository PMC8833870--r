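{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "zoldose cohort report",
  "type": "object",
  "required": ["organ_table", "lesion_doses", "lesion_stats", "plan_summary", "excluded"],
  "properties": {
    "organ_table": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["quantity", "Median", "Mean", "SD"],
        "properties": {
          "quantity": {"type": "string"},
          "Median": {"type": "number"},
          "Mean": {"type": "number"},
          "SD": {"type": "number"}
        }
      }
    },
    "lesion_doses": {"type": "array"},
    "lesion_stats": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["patient_id", "Median", "Mean", "SD"]
      }
    },
    "plan_summary": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["patient_id", "injected_activity_MBq", "mta_GBq", "limiting_organ"],
        "properties": {
          "mta_GBq": {"type": "number", "exclusiveMinimum": 0},
          "limiting_organ": {"type": "string"}
        }
      }
    },
    "excluded": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["patient_id", "reason"]
      }
    }
  }
}
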