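{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "kirstoich fit report",
  "type": "object",
  "required": ["version", "seed", "config", "qc", "groups", "fits",
               "best_model"],
  "properties": {
    "version": {"type": "string"},
    "seed": {"type": "integer"},
    "config": {
      "type": "object",
      "required": ["leak_threshold_uA", "rectification_ratio", "normalizer",
                   "candidates", "bootstrap_B", "seed"],
      "properties": {
        "leak_threshold_uA": {"type": "number"},
        "rectification_ratio": {"type": "number"},
        "noise_floor_uA": {"type": "number"},
        "normalizer": {"type": "string"},
        "candidates": {"type": "array"},
        "bootstrap_B": {"type": "integer"},
        "seed": {"type": "integer"}
      }
    },
    "qc": {
      "type": "object",
      "required": ["total", "included", "leaky", "not_rectifying"],
      "properties": {
        "total": {"type": "integer"},
        "included": {"type": "integer"},
        "leaky": {"type": "integer"},
        "not_rectifying": {"type": "integer"},
        "qc_not_assessable": {"type": "integer"},
        "dropped_batches": {"type": "array"}
      }
    },
    "groups": {"type": "array"},
    "fits": {"type": "array"},
    "bootstrap": {"type": ["array", "null"]},
    "best_model": {"type": "string"}
  }
}
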