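{
  "rows": ["T0", "T1", "T2"],
  "cols": ["green", "amber", "red"],
  "counts": [[0, 22, 125], [6, 53, 49], [24, 74, 28]]
}
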