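{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "nanosift tuning report",
  "type": "object",
  "required": ["report_version", "beta", "n_samples", "aps"],
  "properties": {
    "report_version": {"type": "integer", "const": 1},
    "beta": {"type": "number", "exclusiveMinimum": 0},
    "n_samples": {"type": "integer", "minimum": 0},
    "aps": {
      "type": "object",
      "minProperties": 1,
      "additionalProperties": {
        "type": "object",
        "required": ["cutoffs", "by_length", "histograms"],
        "properties": {
          "cutoffs": {
            "type": "object",
            "required": ["similarity_cutoff", "location_cutoff",
                         "ap_sub_length", "beta", "precision", "recall",
                         "f_beta"],
            "properties": {
              "similarity_cutoff": {"type": "number", "minimum": 0, "maximum": 1},
              "location_cutoff": {"type": "number", "minimum": 0},
              "ap_sub_length": {"type": "integer", "minimum": 1},
              "beta": {"type": "number", "exclusiveMinimum": 0},
              "precision": {"type": "number", "minimum": 0, "maximum": 1},
              "recall": {"type": "number", "minimum": 0, "maximum": 1},
              "f_beta": {"type": "number", "minimum": 0, "maximum": 1}
            }
          },
          "by_length": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["ap_sub_length", "similarity_cutoff",
                           "location_cutoff", "precision", "recall", "f_beta"]
            }
          },
          "histograms": {
            "type": "object",
            "required": ["similarity", "location"],
            "additionalProperties": {
              "type": "object",
              "required": ["breaks", "true", "random"],
              "properties": {
                "breaks": {"type": "array", "items": {"type": "number"}},
                "true": {"type": "array", "items": {"type": "integer"}},
                "random": {"type": "array", "items": {"type": "integer"}}
              }
            }
          }
        }
      }
    },
    "counts": {
      "type": ["object", "null"],
      "additionalProperties": {"type": "integer", "minimum": 0}
    }
  }
}
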