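{
  "region_csv": "sigmoid_cd3_regions.csv",
  "seed": 1
}
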