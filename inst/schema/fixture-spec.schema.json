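{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "ontotriage synthetic-fixture specification",
  "type": "object",
  "properties": {
    "n_concepts_per_axis": { "type": "integer", "minimum": 1 },
    "n_docs": { "type": "integer", "minimum": 0 },
    "doc_length": {
      "type": "array", "items": { "type": "integer", "minimum": 1 },
      "minItems": 2, "maxItems": 2
    },
    "plant_rate": { "type": "number", "minimum": 0 },
    "relevance_intercept": { "type": "number" },
    "relevance_slope": { "type": "number" },
    "n_topics": { "type": "integer", "minimum": 1 },
    "seed": { "type": "integer" }
  },
  "additionalProperties": false
}
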