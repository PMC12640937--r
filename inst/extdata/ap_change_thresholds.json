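{
  "version": "1.0",
  "units": "percent change over vehicle baseline",
  "thresholds": {
    "apd30": {"1": 12.0, "2": 12.1},
    "apd50": {"1": 9.1, "2": 9.7},
    "apd90": {"1": 6.9, "2": 7.5},
    "triangulation": {"1": 9.0, "2": 10.2},
    "stv": {"1": 102.6, "2": 164.3}
  }
}
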