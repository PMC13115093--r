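{
  "criteria_order": ["z_ave", "count_rate", "pdi", "zeta_abs", "conductivity"],
  "weights": [0.15, 0.20, 0.25, 0.15, 0.25],
  "directions": ["cost", "benefit", "cost", "benefit", "cost"],
  "rounding_tolerance": 0.001,
  "seed": 0
}
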