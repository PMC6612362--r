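{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "omeconvert formulary",
  "description": "Data-driven equianalgesic formulary: drugs/routes, oral morphine equivalent conversion factors, transdermal patch band tables, and practical defaults. All dose numbers are decimal; units are fixed by route (mg/24h for oral and subcutaneous, microgram/h for transdermal) and never appear inside numeric fields.",
  "type": "object",
  "required": ["version", "drugs", "factors"],
  "properties": {
    "version": {"type": "string"},
    "drugs": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["drug", "route"],
        "properties": {
          "drug": {"type": "string"},
          "route": {"enum": ["oral", "subcutaneous", "transdermal"]},
          "supported": {"type": "boolean", "default": true},
          "renal_risk": {"type": "boolean", "default": false}
        },
        "additionalProperties": false
      }
    },
    "factors": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["drug", "route", "ome_per_unit"],
        "properties": {
          "drug": {"type": "string"},
          "route": {"enum": ["oral", "subcutaneous"]},
          "ome_per_unit": {"type": "number", "exclusiveMinimum": 0}
        },
        "additionalProperties": false
      }
    },
    "patch_tables": {
      "type": "object",
      "additionalProperties": {
        "type": "array",
        "minItems": 1,
        "items": {
          "type": "object",
          "required": ["strength", "ome_low", "ome_high"],
          "properties": {
            "strength": {"type": "number", "exclusiveMinimum": 0},
            "ome_low": {"type": "number", "exclusiveMinimum": 0},
            "ome_high": {"type": "number", "exclusiveMinimum": 0}
          },
          "additionalProperties": false
        }
      }
    },
    "defaults": {
      "type": "object",
      "properties": {
        "breakthrough_divisor": {"type": "number", "exclusiveMinimum": 0, "default": 6},
        "egfr_warning_threshold": {"type": "number", "exclusiveMinimum": 0, "default": 30},
        "practical_increments": {
          "type": "object",
          "additionalProperties": {"type": "number", "exclusiveMinimum": 0}
        }
      },
      "additionalProperties": false
    }
  },
  "additionalProperties": false
}
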