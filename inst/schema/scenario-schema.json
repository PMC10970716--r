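{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "formularyimpact exclusion scenario",
  "description": "Configuration for the formulary-exclusion impact cascade. Canonical on-disk form is YAML with this structure; JSON is accepted. Percentages may be written as fractions (keys 'fraction', 'share', 'market_share') or percents (keys 'percent', 'share_percent', 'market_share_percent'); they are stored internally as fractions.",
  "type": "object",
  "required": ["name", "population", "formularies", "indication", "share_groups", "outcome_models"],
  "properties": {
    "name": { "type": "string", "minLength": 1 },
    "population": {
      "type": "object",
      "required": ["total", "segments"],
      "properties": {
        "total": { "type": "number", "exclusiveMinimum": 0 },
        "segments": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["name"],
            "properties": {
              "name": { "type": "string" },
              "fraction": { "type": "number", "minimum": 0, "maximum": 1 },
              "percent": { "type": "number", "minimum": 0, "maximum": 100 }
            },
            "oneOf": [ { "required": ["fraction"] }, { "required": ["percent"] } ]
          },
          "description": "Segment fractions must sum to at most 1."
        }
      }
    },
    "formularies": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["name"],
        "properties": {
          "name": { "type": "string" },
          "market_share": { "type": "number", "exclusiveMinimum": 0, "maximum": 1 },
          "market_share_percent": { "type": "number", "exclusiveMinimum": 0, "maximum": 100 }
        },
        "oneOf": [ { "required": ["market_share"] }, { "required": ["market_share_percent"] } ]
      }
    },
    "indication": {
      "type": "object",
      "required": ["name", "prevalence"],
      "properties": {
        "name": { "type": "string" },
        "prevalence": { "$ref": "#/$defs/fraction_range" },
        "eligibility_factors": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["label"],
            "properties": {
              "label": { "type": "string" },
              "fraction": { "type": "number", "exclusiveMinimum": 0, "maximum": 1 },
              "percent": { "type": "number", "exclusiveMinimum": 0, "maximum": 100 }
            },
            "oneOf": [ { "required": ["fraction"] }, { "required": ["percent"] } ]
          }
        },
        "calibration_factor": { "type": "number", "exclusiveMinimum": 0, "maximum": 1, "default": 1.0 },
        "calibration_provenance": { "type": "string" }
      }
    },
    "share_groups": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["group_id", "medications"],
        "properties": {
          "group_id": { "type": "string" },
          "medications": {
            "type": "array",
            "minItems": 1,
            "items": {
              "type": "object",
              "required": ["brand_name", "outcome_model"],
              "properties": {
                "brand_name": { "type": "string" },
                "generic_name": { "type": "string" },
                "outcome_model": { "type": "string" },
                "prescriptions": { "type": "number", "minimum": 0 },
                "share": { "type": "number", "minimum": 0, "maximum": 1 },
                "share_percent": { "type": "number", "minimum": 0, "maximum": 100 },
                "note": { "type": "string" }
              },
              "oneOf": [
                { "required": ["prescriptions"] },
                { "required": ["share"] },
                { "required": ["share_percent"] }
              ]
            }
          }
        }
      },
      "description": "Shares are normalized within each group to sum to exactly 1 at load time (prescription counts are divided by the group total; printed percentages are renormalized by their own sum)."
    },
    "outcome_models": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["id", "discontinuation", "adverse_event_rule"],
        "properties": {
          "id": { "type": "string" },
          "discontinuation": { "$ref": "#/$defs/fraction_range" },
          "adverse_event_rule": {
            "oneOf": [
              {
                "type": "object",
                "required": ["type", "rate"],
                "properties": {
                  "type": { "const": "flat_rate" },
                  "rate": { "$ref": "#/$defs/fraction_range" }
                }
              },
              {
                "type": "object",
                "required": ["type", "event_given_discontinuation", "event_given_switch"],
                "properties": {
                  "type": { "const": "coupled_compound" },
                  "event_given_discontinuation": { "$ref": "#/$defs/fraction_range" },
                  "event_given_switch": { "$ref": "#/$defs/fraction_range" }
                }
              }
            ]
          }
        }
      }
    },
    "output_unit": { "const": "thousands" },
    "annotations": { "type": "object", "description": "Documented, unused inputs." }
  },
  "$defs": {
    "fraction_range": {
      "type": "object",
      "required": ["low", "high"],
      "properties": {
        "low": { "type": "number", "minimum": 0 },
        "high": { "type": "number", "maximum": 1 },
        "unit": { "const": "%" }
      },
      "description": "low <= high; values are fractions unless unit is '%'."
    }
  }
}
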