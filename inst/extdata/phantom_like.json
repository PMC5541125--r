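{
  "pixel_noise": [0.01],
  "feature_jitter_px": [0.25],
  "contour_sigma_px": [0.5],
  "occlusion_frac": [0],
  "occlusion_view": ["LAT"],
  "blur_sigma_px": [0.5],
  "psf_sigma_px": [0.7],
  "distortion": [false]
}
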