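{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "https://dmcurate.r-lib.invalid/schema/map-elements.schema.json",
  "title": "dmcurate disease-map document",
  "type": "object",
  "required": ["elements", "meta"],
  "properties": {
    "elements": {
      "type": "array",
      "items": {
        "oneOf": [
          { "$ref": "#/definitions/compartmentElement" },
          { "$ref": "#/definitions/nodeElement" },
          { "$ref": "#/definitions/edgeElement" }
        ]
      }
    },
    "meta": {
      "type": "object",
      "required": ["created", "source_files", "lexicon", "tool", "version", "audit"],
      "properties": {
        "created": { "type": "string" },
        "source_files": { "type": "array", "items": { "type": "string" } },
        "lexicon": { "type": "string" },
        "tool": { "type": "string" },
        "version": { "type": "string" },
        "audit": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["edge_id", "status", "timestamp"],
            "properties": {
              "edge_id": { "type": "string" },
              "status": { "enum": ["accepted", "declined", "further_inspection_needed"] },
              "note": { "type": ["string", "null"] },
              "timestamp": { "type": "string" }
            }
          }
        }
      }
    }
  },
  "definitions": {
    "position": {
      "type": "object",
      "required": ["x", "y"],
      "properties": { "x": { "type": "number" }, "y": { "type": "number" } }
    },
    "compartmentElement": {
      "type": "object",
      "required": ["group", "data", "position"],
      "properties": {
        "group": { "const": "nodes" },
        "position": { "$ref": "#/definitions/position" },
        "data": {
          "type": "object",
          "required": ["id", "label", "bounds"],
          "properties": {
            "id": { "type": "string", "minLength": 1 },
            "label": { "type": "string" },
            "bounds": {
              "type": "array",
              "minItems": 4,
              "maxItems": 4,
              "items": { "type": "number" }
            }
          }
        }
      }
    },
    "nodeElement": {
      "type": "object",
      "required": ["group", "data", "position"],
      "properties": {
        "group": { "const": "nodes" },
        "position": { "$ref": "#/definitions/position" },
        "data": {
          "type": "object",
          "required": ["id", "label", "parent"],
          "properties": {
            "id": { "type": "string", "minLength": 1 },
            "label": { "type": "string" },
            "parent": { "type": "string", "minLength": 1 }
          }
        }
      }
    },
    "edgeElement": {
      "type": "object",
      "required": ["group", "data", "classes"],
      "properties": {
        "group": { "const": "edges" },
        "classes": { "enum": ["neutral", "inhibit", "activate", "undefined", "incoherent"] },
        "data": {
          "type": "object",
          "required": ["id", "source", "target", "weight", "review_status", "references"],
          "properties": {
            "id": { "type": "string", "minLength": 1 },
            "source": { "type": "string" },
            "target": { "type": "string" },
            "weight": { "type": "integer", "minimum": 1 },
            "review_status": {
              "enum": ["unreviewed", "accepted", "declined", "further_inspection_needed"]
            },
            "references": {
              "type": "array",
              "minItems": 1,
              "items": {
                "type": "object",
                "required": ["pmid", "year", "sentence", "verbs", "verb_categories"],
                "properties": {
                  "pmid": { "type": "integer", "minimum": 1 },
                  "year": { "type": "integer", "minimum": 1800, "maximum": 2100 },
                  "sentence": { "type": "string", "minLength": 1 },
                  "verbs": { "type": "array", "items": { "type": "string" } },
                  "verb_categories": {
                    "type": "array",
                    "items": { "enum": ["activate", "inhibit", "neutral", "undefined"] }
                  }
                }
              }
            }
          }
        }
      }
    }
  }
}
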