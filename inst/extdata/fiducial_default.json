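{
  "bead_centers": [[0, 0, 40], [28, 0, 52], [0, 20, 70]],
  "pin_tip": [0, 0, -80]
}
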