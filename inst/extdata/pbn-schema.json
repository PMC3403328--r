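{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "Probabilistic Boolean network",
  "type": "object",
  "required": ["n", "m", "K", "p", "representation"],
  "properties": {
    "n": { "type": "integer", "minimum": 1 },
    "m": { "type": "integer", "minimum": 0 },
    "K": { "type": "integer", "minimum": 1 },
    "p": { "type": "number", "minimum": 0, "exclusiveMaximum": 1 },
    "representation": { "enum": ["per_gene", "constituents"] },
    "genes": {
      "type": "array",
      "items": {
        "type": "array",
        "minItems": 1,
        "items": {
          "type": "object",
          "required": ["parents", "table", "c"],
          "properties": {
            "parents": { "type": "array", "minItems": 1, "items": { "type": "integer", "minimum": 1 } },
            "table": { "type": "array", "items": { "enum": [0, 1] } },
            "c": { "type": "number", "minimum": 0, "maximum": 1 }
          }
        }
      }
    },
    "constituents": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["q", "functions"],
        "properties": {
          "q": { "type": "number", "minimum": 0, "maximum": 1 },
          "functions": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["parents", "table"],
              "properties": {
                "parents": { "type": "array", "minItems": 1, "items": { "type": "integer", "minimum": 1 } },
                "table": { "type": "array", "items": { "enum": [0, 1] } }
              }
            }
          }
        }
      }
    }
  },
  "oneOf": [
    { "properties": { "representation": { "const": "per_gene" } }, "required": ["genes"] },
    { "properties": { "representation": { "const": "constituents" } }, "required": ["constituents"] }
  ]
}
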