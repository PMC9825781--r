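{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "ontotriage concept lexicon (JSON dialect)",
  "type": "array",
  "items": {
    "type": "object",
    "required": ["id", "axis", "preferred_label"],
    "properties": {
      "id": { "type": "string", "minLength": 1 },
      "axis": {
        "type": "string",
        "enum": ["BMV", "CE", "CL", "CT", "CHEM", "DIS", "GL", "ORG", "PG"]
      },
      "preferred_label": { "type": "string", "minLength": 1 },
      "synonyms": { "type": "array", "items": { "type": "string" } },
      "xrefs": { "type": "array", "items": { "type": "string" } }
    },
    "additionalProperties": false
  }
}
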