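{
  "$comment": "Structural schema for runmech-results documents; enforced in R by validate_results().",
  "type": "object",
  "required": ["format", "version", "meta", "windows", "steps"],
  "properties": {
    "format": {"const": "runmech-results"},
    "version": {"type": "integer"},
    "meta": {
      "type": "object",
      "required": ["units"],
      "properties": {
        "units": {
          "type": "object",
          "required": ["time", "force", "loading_rate", "impulse", "stiffness", "work", "sf", "df", "dz"]
        }
      }
    },
    "windows": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["window", "n_steps", "w_pot", "w_kin", "w_ext", "w_int", "w_tot"]
      }
    },
    "steps": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["step", "t_c", "t_f", "sf", "df", "f_v_max", "has_impact", "i_v"],
        "properties": {"has_impact": {"type": "boolean"}}
      }
    }
  }
}
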