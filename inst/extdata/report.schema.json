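{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Near-miss indicator report",
  "type": "array",
  "items": {
    "type": "object",
    "required": ["set_id", "counts", "indicators", "presentation"],
    "properties": {
      "set_id": {"type": "string"},
      "counts": {
        "type": "object",
        "required": ["n_near_miss", "n_deaths_identified", "n_deaths_missed", "n_smo", "live_births"],
        "properties": {
          "n_near_miss": {"type": "integer", "minimum": 0},
          "n_deaths_identified": {"type": "integer", "minimum": 0},
          "n_deaths_missed": {"type": "integer", "minimum": 0},
          "n_smo": {"type": "integer", "minimum": 0},
          "live_births": {"type": "integer", "minimum": 1}
        }
      },
      "indicators": {
        "type": "object",
        "required": ["mnm_ratio_per_1000", "smo_ratio_per_1000", "mortality_index_pct", "mnm_to_md_ratio"],
        "properties": {
          "mnm_ratio_per_1000": {"type": "number", "minimum": 0},
          "smo_ratio_per_1000": {"type": "number", "minimum": 0},
          "mortality_index_pct": {"type": "number", "minimum": 0, "maximum": 100},
          "mnm_to_md_ratio": {"type": ["number", "null"], "minimum": 0}
        }
      },
      "presentation": {
        "type": "object",
        "description": "Rounded half-away-from-zero: 1 decimal for ratios and index, 2 for MNM:MD.",
        "properties": {
          "mnm_ratio_per_1000": {"type": "number"},
          "smo_ratio_per_1000": {"type": "number"},
          "mortality_index_pct": {"type": "number"},
          "mnm_to_md_ratio": {"type": ["number", "null"]}
        }
      }
    }
  }
}
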