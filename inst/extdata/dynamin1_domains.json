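{
  "Gdomain": [[33, 293]],
  "BSE": [[1, 32], [294, 320], [711, 746]],
  "Stalk": [[321, 499], [643, 710]],
  "PH": [[500, 642]]
}
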