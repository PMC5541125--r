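{
  "sid": [980],
  "pixel_size": [0.224],
  "detector_diameter": [230],
  "image_shape": [1027, 1027],
  "principal_point": [514, 514]
}
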