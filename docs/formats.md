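# File formats

All JSON files are written by `jsonlite` with full double precision.

## Meshes (`.stl`)

Binary or ASCII STL, millimetres. The package writes ASCII. STL has no face
attributes, so fracture-surface labels are stored in a sidecar
`<name>.stl.labels.json`:

```json
{ "fracture_faces": [12, 13, 14] }
```

with 1-based face indices in the order faces appear in the STL.

## Rigid transforms (`*.json`)

```json
{ "type": "rigid_transform", "matrix": [[r,r,r,t], [r,r,r,t], [r,r,r,t], [0,0,0,1]] }
```

Row-major homogeneous 4x4; rotation validated to be orthonormal within 1e-6
on read.

## C-arm configuration (`carm_default.json`)

`sid` (mm), `pixel_size` (mm/px), `detector_diameter` (mm), `image_shape`
(rows, cols), `principal_point` (u, v px), optional `distortion`
(`coefficients` k1, k2 in px^-2, px^-4 and `center` px; synthesis only).

## Fiducial geometry (`fiducial_default.json`)

`bead_centers`: 3 x 3 bead centres (mm) and `pin_tip` (mm), both in the
registration-tool frame (coincident with the pin frame).

## Feature detections

`points`: 4 x 2 pixel coordinates, `labels`: permutation of
`bead1 bead2 bead3 pin_tip`. Used by the manual detection pathway.

## Calibration result

`degree`, `coeffs_u`, `coeffs_v` (bivariate polynomial on normalised
coordinates), `norm` (centering/scaling), `fit_rms` (px),
`pixel_size_estimate` (mm/px), `holdout_rms` (px).

## Registration result

`fragment_pose` and `pin_to_fragment` as 4x4 row-major matrices,
`final_cost` (px^2), `iterations`, `converged`, `per_view_rms` (px).

## Noise profiles (`clean.json`, `phantom_like.json`, `cadaver_like.json`)

Fields of `noise_profile()`: `pixel_noise` (fraction of full scale),
`feature_jitter_px`, `contour_sigma_px`, `occlusion_frac`,
`occlusion_view`, `blur_sigma_px`, `psf_sigma_px`, `distortion`.

## Images

16-bit grayscale TIFF (or PNG), values in [0, 1]; row = image v, column =
image u, pixel centres at integer coordinates starting at (1, 1).

## Experiment table (CSV)

One row per (seed, fragment): `stre_mean`, `stre_sd` (mm), `final_cost`
(px^2), `converged`, `iterations`, per-view pose reprojection RMS (px),
`pixel_size` (mm/px) and `error` (empty when the run succeeded).
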