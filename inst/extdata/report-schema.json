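{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "idpensemble variant-comparison report",
  "type": "object",
  "required": ["config", "variants", "dimensions", "interactions", "landscape"],
  "properties": {
    "config": {
      "type": "object",
      "required": ["endpoint_atom", "rs_convention", "contact_cutoff",
                   "hb_r0", "hb_k", "cation_atom", "cation_cutoff",
                   "grid_size", "max_level"]
    },
    "variants": {"type": "array"},
    "dimensions": {"type": "array"},
    "interactions": {
      "type": "object",
      "required": ["salt_bridge_rows", "cation_pi_rows"]
    },
    "landscape": {
      "type": "object",
      "required": ["explained_variance_pc12", "basins"]
    }
  }
}
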