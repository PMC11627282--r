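{
  "$comment": "lidcontour photo-annotation schema, version 1.0. Informal JSON-schema-style description of the files read by read_photo_annotation() and written by write_photo_annotation(). All coordinates are raw image pixels, raster convention (y grows downward).",
  "type": "object",
  "required": ["schema_version", "patient_id", "timepoint", "sex", "ptotic_side", "eyes"],
  "properties": {
    "schema_version": {"type": "string", "const": "1.0"},
    "patient_id": {"type": "string", "minLength": 1},
    "timepoint": {"enum": ["preop", "postop6m"]},
    "sex": {"enum": ["male", "female"], "$comment": "selects the white-to-white calibration constant: 11.77 mm (male) or 11.64 mm (female)"},
    "ptotic_side": {"enum": ["right", "left"]},
    "eyes": {
      "type": "object",
      "required": ["right", "left"],
      "properties": {
        "right": {"$ref": "#/definitions/eye"},
        "left": {"$ref": "#/definitions/eye"}
      }
    },
    "image_path": {"type": ["string", "null"], "$comment": "optional path of the underlying raster image"},
    "metadata": {"type": "object", "$comment": "free key-value pairs (e.g. levator function); not used computationally"}
  },
  "definitions": {
    "eye": {
      "type": "object",
      "required": ["side", "pupil_center", "limbus_nasal", "limbus_temporal", "lateral_canthus", "margin"],
      "properties": {
        "side": {"enum": ["right", "left"]},
        "pupil_center": {"$ref": "#/definitions/point"},
        "pupil_diameter": {"type": "number", "exclusiveMinimum": 0, "$comment": "optional, pixels"},
        "limbus_nasal": {"$ref": "#/definitions/point"},
        "limbus_temporal": {"$ref": "#/definitions/point"},
        "lateral_canthus": {"$ref": "#/definitions/point"},
        "margin": {
          "type": "object",
          "required": ["x", "y"],
          "properties": {
            "x": {"type": "array", "items": {"type": "number"}, "minItems": 2},
            "y": {"type": "array", "items": {"type": "number"}, "minItems": 2}
          },
          "$comment": "ordered polyline tracing the upper-eyelid margin"
        }
      }
    },
    "point": {
      "type": "array",
      "items": {"type": "number"},
      "minItems": 2,
      "maxItems": 2,
      "$comment": "[x, y] in pixels, finite"
    }
  }
}
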