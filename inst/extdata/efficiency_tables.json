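{
  "comment": "Default position-dependent editing-efficiency models. Positions are 1-based protospacer positions, PAM-distal = 1. 'relative' values are scaled by 'max_efficiency' (percent) to give the predicted absolute editing efficiency per position. These defaults are placeholders estimated from published editor windows; override with your own calibration where available.",
  "ABE": {
    "max_efficiency": 60,
    "relative": { "4": 0.55, "5": 0.85, "6": 1.0, "7": 0.9, "8": 0.7, "9": 0.45 }
  },
  "BE3": {
    "max_efficiency": 50,
    "relative": { "4": 0.7, "5": 1.0, "6": 0.9, "7": 0.6, "8": 0.4 }
  }
}
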