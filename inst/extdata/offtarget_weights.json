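{
  "comment": "Position-specific mismatch penalty weights for the per-hit off-target score (position 1 = PAM-distal). hit score = 100 * prod(1 - w[p]) * 1/(((d_denominator - dbar)/d_denominator) * d_multiplier + d_offset) * 1/m^count_exponent, where dbar is the mean pairwise distance between mismatch positions and m the mismatch count; single-mismatch hits take distance and count terms of 1. Editable config.",
  "weights": [0.0, 0.0, 0.014, 0.0, 0.0, 0.395, 0.317, 0.0, 0.389, 0.079,
              0.445, 0.508, 0.613, 0.851, 0.732, 0.828, 0.615, 0.804, 0.685, 0.583],
  "d_denominator": 19,
  "d_multiplier": 4,
  "d_offset": 1,
  "count_exponent": 2
}
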