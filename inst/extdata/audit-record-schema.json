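{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "omeconvert audit record",
  "description": "One logged calculation. The schema is closed: no field outside this list is accepted, so patient-identifiable free text cannot enter the log. Records are append-only with gapless monotonically increasing record_id.",
  "type": "object",
  "required": ["record_id", "timestamp", "kind", "index_drug", "index_route", "index_dose", "status", "formulary_version"],
  "properties": {
    "record_id": {"type": "integer", "minimum": 1},
    "timestamp": {"type": "string", "pattern": "^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}Z$"},
    "kind": {"enum": ["conversion", "breakthrough"]},
    "index_drug": {"type": "string"},
    "index_route": {"enum": ["oral", "subcutaneous", "transdermal"]},
    "index_dose": {"type": "number", "exclusiveMinimum": 0},
    "target_drug": {"type": ["string", "null"]},
    "target_route": {"enum": ["oral", "subcutaneous", "transdermal", null]},
    "status": {"enum": ["ok", "no_guideline_equivalence", "unsupported_drug"]},
    "ome": {"type": ["number", "null"]},
    "exact_dose": {"type": ["number", "null"]},
    "practical_dose": {"type": ["number", "null"]},
    "warnings": {
      "type": "array",
      "items": {"enum": ["renal_caution", "below_smallest_patch", "above_largest_patch", "large_dose"]}
    },
    "indication": {"enum": ["cancer pain", "non-cancer pain", "end of life care", "unspecified", null]},
    "formulary_version": {"type": "string"}
  },
  "additionalProperties": false
}
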