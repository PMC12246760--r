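{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "swipesense session log",
  "description": "One participant x game play session: per-swipe gesture metrics with full touch traces, plus free-running device-motion streams. Coordinates use a bottom-left origin in the session's orientation (pixels, y up); pressure is a fingertip contact-area proxy in [0,1]; swipe_event_time is anchored at game launch, swipe_start_time/swipe_end_time at level load (seconds).",
  "type": "object",
  "required": ["participant_id", "game", "orientation", "screen_dims", "session_limit", "gameplay_window", "swipes", "sensors"],
  "properties": {
    "participant_id": {"type": "string"},
    "game": {"enum": ["puzzle", "runner", "slicer"]},
    "orientation": {"enum": ["landscape", "portrait"]},
    "screen_dims": {"type": "array", "items": {"type": "number", "minimum": 0}, "minItems": 2, "maxItems": 2},
    "session_limit": {"type": "number", "minimum": 0},
    "gameplay_window": {"type": "array", "items": {"type": "number", "minimum": 0}, "minItems": 2, "maxItems": 2},
    "swipes": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["swipe_ID", "swipe_event_time", "swipe_start_time", "swipe_end_time", "swipe_start_pos", "swipe_end_pos", "swipe_pos", "swipe_start_press", "swipe_end_press", "swipe_start_press_variance", "swipe_end_press_variance", "swipe_press", "swipe_press_variance", "swipe_speed", "swipe_duration", "swipe_distance", "swipe_direction", "time_between_swipes"],
        "properties": {
          "swipe_ID": {"type": "integer"},
          "swipe_event_time": {"type": "number", "minimum": 0},
          "swipe_start_time": {"type": "number"},
          "swipe_end_time": {"type": "number"},
          "swipe_start_pos": {"$ref": "#/definitions/xy"},
          "swipe_end_pos": {"$ref": "#/definitions/xy"},
          "swipe_pos": {
            "description": "Touch trace: [t_since_swipe_start_s, x_px, y_px, press] per point, times nondecreasing.",
            "type": "array",
            "items": {"type": "array", "items": {"type": "number"}, "minItems": 4, "maxItems": 4}
          },
          "swipe_start_press": {"type": "number", "minimum": 0, "maximum": 1},
          "swipe_end_press": {"type": "number", "minimum": 0, "maximum": 1},
          "swipe_start_press_variance": {"type": "number", "minimum": 0},
          "swipe_end_press_variance": {"type": "number", "minimum": 0},
          "swipe_press": {"type": "number", "minimum": 0, "maximum": 1},
          "swipe_press_variance": {"type": "number", "minimum": 0},
          "swipe_speed": {"type": "number", "minimum": 0},
          "swipe_duration": {"type": "number", "minimum": 0},
          "swipe_distance": {"type": "number", "minimum": 0},
          "swipe_direction": {
            "description": "Quantized direction for puzzle/runner swipes; 'none' for the slicer.",
            "enum": ["up", "down", "left", "right", "none"]
          },
          "time_between_swipes": {"type": ["number", "null"], "minimum": 0}
        }
      }
    },
    "sensors": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["stream", "t", "x", "y", "z"],
        "properties": {
          "stream": {"enum": ["accelerometer", "gyroscope"]},
          "t": {"type": "array", "items": {"type": "number", "minimum": 0}},
          "x": {"type": "array", "items": {"type": "number"}},
          "y": {"type": "array", "items": {"type": "number"}},
          "z": {"type": "array", "items": {"type": "number"}}
        }
      }
    }
  },
  "definitions": {
    "xy": {"type": "array", "items": {"type": "number"}, "minItems": 2, "maxItems": 2}
  }
}
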