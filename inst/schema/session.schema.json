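{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "percross session",
  "description": "Single-file JSON mirror of a perceptual-crossing session: world configuration, trial roster, click events with PAS responses, and optional avatar trajectories.",
  "type": "object",
  "required": ["world", "trials", "events"],
  "properties": {
    "world": {
      "type": "object",
      "required": ["space_length", "object_length", "shadow_offset",
                   "trial_duration", "tick"],
      "properties": {
        "space_length": {"type": "number", "exclusiveMinimum": 0},
        "object_length": {"type": "number", "exclusiveMinimum": 0},
        "shadow_offset": {"type": "number", "minimum": 0},
        "shadow_sign": {"enum": [1, -1]},
        "trial_duration": {"type": "number", "exclusiveMinimum": 0},
        "tick": {"type": "number", "exclusiveMinimum": 0},
        "static_positions": {
          "type": "array", "items": {"type": "number"},
          "minItems": 2, "maxItems": 2
        }
      }
    },
    "trials": {
      "type": "object",
      "description": "Column-oriented trial roster.",
      "required": ["team_id", "trial_number"],
      "properties": {
        "team_id": {"type": "array", "items": {"type": "integer"}},
        "trial_number": {"type": "array", "items": {"type": "integer"}}
      }
    },
    "events": {
      "type": "object",
      "description": "Column-oriented click events; one entry per click. null encodes an absent target or PAS.",
      "required": ["team_id", "trial_number", "player", "click_time_s",
                   "click_position"],
      "properties": {
        "team_id": {"type": "array", "items": {"type": "integer"}},
        "trial_number": {"type": "array", "items": {"type": "integer"}},
        "player": {"type": "array", "items": {"enum": [1, 2]}},
        "click_time_s": {"type": "array", "items": {"type": "number", "minimum": 0}},
        "click_position": {"type": "array", "items": {"type": "number", "minimum": 0}},
        "target": {
          "type": "array",
          "items": {"enum": ["other_avatar", "shadow", "static", "unknown", null]}
        },
        "pas": {"type": "array", "items": {"enum": [1, 2, 3, 4, null]}}
      }
    },
    "trajectories": {
      "type": "object",
      "description": "Optional long-format avatar trajectories at native timestamps.",
      "properties": {
        "team_id": {"type": "array", "items": {"type": "integer"}},
        "trial_number": {"type": "array", "items": {"type": "integer"}},
        "time_s": {"type": "array", "items": {"type": "number", "minimum": 0}},
        "player": {"type": "array", "items": {"enum": [1, 2]}},
        "avatar_position": {"type": "array", "items": {"type": "number", "minimum": 0}}
      }
    }
  }
}
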