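{
  "green_vol": [500, 600],
  "green_time": [0.85, 1.15],
  "amber_vol": [400, 700],
  "amber_time": [0.55, 1.45]
}
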