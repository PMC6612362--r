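{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "omeconvert CLI conversion result (--json)",
  "type": "object",
  "required": ["status", "formulary_version", "warnings"],
  "properties": {
    "status": {"enum": ["ok", "no_guideline_equivalence", "unsupported_drug"]},
    "formulary_version": {"type": "string"},
    "ome_mg_per_24h": {"type": ["number", "null"]},
    "exact_target_dose": {"type": ["number", "null"]},
    "practical_target_dose": {"type": ["number", "null"]},
    "target_unit": {"enum": ["mg/24h", "microgram/h", null]},
    "warnings": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["code", "message"],
        "properties": {
          "code": {"enum": ["renal_caution", "below_smallest_patch", "above_largest_patch", "large_dose"]},
          "message": {"type": "string"}
        },
        "additionalProperties": false
      }
    }
  },
  "additionalProperties": false
}
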