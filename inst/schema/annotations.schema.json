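{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "ontotriage per-document annotation export (one object per JSONL line)",
  "type": "object",
  "required": ["doc_id", "annotations"],
  "properties": {
    "doc_id": { "type": "string", "minLength": 1 },
    "annotations": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["exact", "concept_id", "preferred_label", "axis", "field", "start", "end"],
        "properties": {
          "exact": { "type": "string" },
          "concept_id": { "type": "string" },
          "preferred_label": { "type": ["string", "null"] },
          "axis": {
            "type": ["string", "null"],
            "enum": ["BMV", "CE", "CL", "CT", "CHEM", "DIS", "GL", "ORG", "PG", null]
          },
          "field": { "type": "string", "enum": ["title", "abstract", "body", "keywords"] },
          "start": { "type": "integer", "minimum": 0 },
          "end": { "type": "integer", "minimum": 1 }
        }
      }
    }
  }
}
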