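{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "Cephalometric tracing submission",
  "description": "One student's tracing of one lateral cephalogram as exported by the tracing application. Coordinates are image pixels, x increasing anteriorly (patient faces right), y increasing caudally. Timestamps are ISO-8601 UTC.",
  "type": "object",
  "required": ["subject", "image", "device", "first_placed", "last_placed", "landmarks"],
  "properties": {
    "subject": { "type": "string", "description": "Pseudonym or plain name of the student." },
    "image": { "type": "string", "description": "Cephalogram identifier, e.g. \"A\" or \"B\"." },
    "device": { "enum": ["tablet", "desktop"] },
    "gender": { "enum": ["female", "male", "unknown"], "default": "unknown" },
    "order": { "type": "integer", "enum": [0, 1], "description": "0 if this is the student's first analysis.", "default": 0 },
    "capture": { "enum": ["dicom", "screenshot"], "default": "dicom", "description": "Whether the tracing was made on the DICOM image or on a screenshot of it." },
    "first_placed": { "type": "string", "format": "date-time" },
    "last_placed": { "type": "string", "format": "date-time" },
    "landmarks": {
      "type": "array",
      "maxItems": 33,
      "items": {
        "type": "object",
        "required": ["name", "x", "y"],
        "properties": {
          "name": { "type": "string" },
          "x": { "type": "number", "minimum": 0 },
          "y": { "type": "number", "minimum": 0 }
        }
      }
    }
  }
}
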