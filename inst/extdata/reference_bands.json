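{
  "heaping": {
    "breaks": [0, 0.6, 0.8, 1.3, 1.5],
    "bands": ["improbable", "probable", "plausible", "probable", "improbable"]
  },
  "sb_d01": {
    "breaks": [0, 1.0, 1.7, 3.0, 4.0],
    "bands": ["improbable", "probable", "plausible", "probable", "improbable"]
  },
  "sb_week": {
    "breaks": [0, 0.5, 1.0, 1.9, 2.4],
    "bands": ["improbable", "probable", "plausible", "probable", "improbable"]
  },
  "d01_d26": {
    "breaks": [0, 2.4],
    "bands": ["under-reported", "plausible"]
  }
}
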