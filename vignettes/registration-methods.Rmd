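---
title: "Fiducial-based 2D/3D registration for fluoroscopy-guided fracture surgery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fiducial-based 2D/3D registration for fluoroscopy-guided fracture surgery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluororeg)
```

## The problem

In percutaneous fracture-reduction surgery, bone fragments are manipulated
through orthopaedic pins while the surgeon navigates on pre-operative CT
models. Because the pins are inserted *after* the CT scan, the rigid
transform between each pin and the fragment it holds — the pin-to-fragment
transform — must be measured in the operating theatre. fluororeg implements
an intra-operative measurement of that transform from two calibrated
fluoroscopic views: a registration tool (RT) with three radiopaque beads is
mounted on the pin (their coordinate frames coincide by construction), both
views are posed relative to the RT from the bead and pin-tip projections,
and the CT-derived fragment mesh is then registered to the bone contours
segmented in the same views. Everything downstream (optical tracking, robot
control) consumes the resulting `pin_to_fragment` transform; everything
upstream (C-arm calibration) exists to make the projection model accurate.

## Imaging model

The C-arm is a pinhole camera: X-ray source at the origin, optical axis
+z, detector plane at `z = SID` (source-to-image distance, the focal
length; 980 mm by default). A world point `X` maps to pixels as

    u = (x * SID / z) / PS + u0,   v = (y * SID / z) / PS + v0

with `PS` the detector pixel size (0.224 mm by default) and `(u0, v0)` the
principal point at the detector centre. The default configuration models a
mobile C-arm with a 230-mm image intensifier. Image intensifiers are not
flat panels: the mapping of the image onto the curved input phosphor
stretches the periphery radially. fluororeg models that stretching, on the
synthesis side, as an even-power radial polynomial
`r' = r (1 + k1 r^2 + k2 r^4)` about the distortion centre; the *correction*
side never assumes this form (see Calibration), so the two sides cannot
cancel by construction.

Angles are degrees and lengths millimetres at every API surface; rotations
are stored as 3x3 matrices inside `rigid_transform` objects.

## Calibration

One image of a ball-bearing grid phantom lying on the detector (22-mm pitch,
10-mm bearings, 7x7 — the largest square grid at that pitch that fits a
230-mm circular field) yields both the distortion correction and the pixel
size:

1. `segment_beads()`: Otsu threshold, connected components,
   intensity-weighted centroids.
2. `match_grid()`: similarity pre-alignment (translation plus an in-plane
   rotation search over ±10°), then nearest-node assignment to the ideal
   lattice; the assignment must be bijective.
3. `fit_distortion()`: global least-squares bivariate polynomial (total
   degree 3 by default, configurable 2–5) mapping distorted to ideal
   coordinates, one polynomial per output coordinate, on normalised
   coordinates for conditioning. Cubic is the default because it holds the
   border-ring hold-out residual below 0.1 px against the synthesis-side
   radial model in our simulations; the hold-out residual (fit interior,
   test border ring) is the shipped quality metric.
4. `estimate_pixel_size()`: spacing divided by the mean pixel distance of
   lattice-adjacent bead pairs, under unit magnification (the grid lies on
   the detector). The estimate deliberately uses the *detected* pitch, not
   the polynomial-corrected one: the correction's target lattice is built
   from the nominal pixel size, so measuring its output would merely return
   the nominal value.

## View pose estimation

`detect_features()` finds the three beads (round bright components) and the
pin (elongated component) above a fixed threshold chosen between the bone
and metal intensity levels. The pin tip is localised to sub-pixel precision
by fitting the pin centreline — per axial station, the midpoint of the two
half-maximum wall crossings of the lateral intensity profile, which is
invariant to the differing backgrounds on either side — and intersecting the
axial intensity profile's half-maximum along it. Bead labels and the tip
end are resolved by trying all assignments and keeping the one with the
lowest perspective-4-point reprojection RMS. A detections-JSON bypass
(`read_detections()`) supports manually identified features.

`estimate_image_pose()` solves perspective-3-point for the beads (Grunert
quartic, built by exact polynomial elimination and polished by Newton
iteration), disambiguates the up-to-four solutions by the pin-tip
reprojection (20-px gate), then refines all four correspondences jointly by
Levenberg–Marquardt. The refinement uses all four points; the pin tip is
not only a disambiguator, because with three points the solution is exactly
determined and noise has nowhere to average.

## Contour registration

The fragment pose is estimated by minimising, over the two views,

    C(theta) = sum_views mean_i d(s_i(theta), spline_view)^2

where `s_i` are samples of the projected occluding contour of the mesh at
pose `theta` and `d` is the closest-point distance (px) to the segmented
contour's spline. Implementation choices:

* **Occluding contour.** Mesh edges whose adjacent faces change facing sign
  under the current view, chained into loops; long projected edges are
  subdivided (the interpolated points stay on the mesh silhouette), since
  a cubic spline through sparse polygon vertices would bulge away from the
  true piecewise-straight outline and bias everything downstream. Samples
  are filtered to the *visible* outline by a winding-number test (a small
  outward step must leave the projected union), so interior fold contours
  of non-convex fragments never enter the cost. Because the samples are 3-D points on the
  mesh, pose derivatives need only point projection; the rasterised
  mask-plus-border-following route (`extract_silhouette()`) is used where
  an ordered image contour is the product itself.
* **Segmentation.** `segment_contour()` moves each sample of the initial
  (model-projected) contour along its normal to the best intensity edge
  within ±15 px: the candidate edges are local gradient maxima above a
  threshold and above 40% of the profile's strongest gradient; among them
  the nearest to the initial position wins (a neighbouring structure such
  as the pin often carries a *stronger* edge than the bone being tracked).
  The crossing is then refined to sub-pixel precision as the half-maximum
  of the local intensity step, which is phase-invariant under bilinear
  sampling. Samples with no acceptable edge, samples on high-curvature
  corners (turning > 15° per sample, where normals are ambiguous), and
  samples forced by an occlusion mask are dropped; if more than 60% drop,
  the view is declared unsegmentable (the situation real lateral views
  produce when fragments overlap). Dropped spans are *bridged* by the
  spline but flagged unsupported, and registration ignores residuals whose
  closest point falls on an unsupported span — occluded regions are
  dropped, not interpolated.
* **Optimisation.** Alternation of correspondence update (re-extracting the
  silhouette sample set at the current pose) and a damped Gauss–Newton step
  on the 6-DOF pose (rotation-vector increment, numerical forward-difference
  Jacobian, Marquardt damping with accept/reject). Samples farther than
  3x the median distance (+1 px) are trimmed per iteration. Convergence:
  relative cost change below 1e-8 or 200 iterations; a fully damped step
  that cannot change the cost is a fixed point, not a failure; five
  consecutive rejected steps raise a non-convergence error carrying the
  cost trace.
* **Initialisation.** The surgeon's manual coarse alignment is replaced by
  `coarse_align()`: a seeded randomised search (default 200 candidates,
  ±15 mm / ±15° about the mesh centroid) around a centroid-based guess
  (two-view triangulation of the contour centroids), scored by the
  registration cost. The sample budget is spent in shrinking re-centred
  rounds with axis-aligned pattern probes, and the best sample receives a
  few damped Gauss-Newton iterations — uniform 6-DOF sampling alone
  essentially never tracks the long, shallow cost valley that the
  between-views depth direction produces. A manual initial pose can be
  supplied instead.

The two views are weighted equally and the cost is in image pixels; no
view weighting is applied.

## Evaluation

`sample_fracture_surface()` draws points area-uniformly on the
fracture-labelled faces (deterministic per seed; default n = 100, a choice
dense enough that the sample mean is stable to a few hundredths of a
millimetre). `compute_stre()` reports the surface target registration error
— per-point distances between the ground-truth-posed and estimated-posed
samples — as mean ± sd *across points*; experiment tables then average
those means *across runs* and report both levels. Rotational reduction
error uses the geodesic angle of `R_achieved' R_desired`, the standard
replacement for protractor-style angle reading on radiographs, and
translational error is the RMSE of probe-point displacements. The robot
target-pose chain composes tracked robot-to-pin, image-to-fragment and
planned poses in exactly that order; a guard test pins the order down.

## The synthetic phantom

`generate_phantom()` builds a three-fragment distal-femur fracture
analogue: a shaft flaring into a two-lobed condylar mass, split by a
transverse cut (FEM vs distal block) and a sagittal (T) or oblique (Y)
distal cut (F1 vs F2). All cut faces are labelled fracture surface; the
fragments are watertight by construction (structured rings zipped by
angular parameter, planar caps and cut bands shared exactly), so the three
fragment volumes add to the uncut solid's volume to numerical precision.
The shaft cross-section is deliberately *not* circular — 8% ellipticity, a
12% posterior longitudinal ridge, 4-mm anterior bow — because a surface of
revolution leaves rotation about its own axis unobservable in silhouettes;
real femoral shafts share all three features. Vertices can be quantised to
the CT voxel grid (0.58 x 0.58 x 0.75 mm) to emulate CT-derived meshes.
Pins are placed per fragment with seeded insertion-axis jitter; the
fragment's world frame is its pin/RT frame, which is exactly the frame the
intra-operative registration must recover.

`render_view()` draws the filled projected silhouette of the fragment
(anti-aliased with a 1-px coverage ramp; a hard fill would quantise the
edge the segmentation is asked to localise), the pin as a tapered capsule
whose apex is the exact projected tip, and the beads as soft disks, then
applies a 0.7-px detector PSF, optional radial distortion, blur and
Gaussian pixel noise. Intensity levels are chosen so metal over bone never
saturates (clipping would bias sub-pixel feature localisation). This is
silhouette shading, not X-ray transport: every downstream consumer uses
edges and blobs only, and physical attenuation would change none of them.
Ground truth (camera pose, feature pixels, silhouette) is recorded
pre-degradation.

Views are AP (90°) and LAT (60°) of a C-arm orbiting the pin axis; the
source-to-scene standoff is auto-fitted (600–945 mm) so the scene fills at
most 95% of the detector radius.

### Noise profiles

The real study's laboratory and surgical acquisitions are not parametric,
so the package declares two named profiles as calibration knobs, stored as
versioned JSON:

| profile | pixel noise | feature jitter | contour sigma | occlusion |
|---|---|---|---|---|
| phantom-like | 1% | 0.25 px | 0.5 px | none |
| cadaver-like | 2% | 0.5 px | 1.5 px | 25% of the LAT contour |

The cadaver-like profile's heavier contour noise and lateral-view occlusion
mirror the two failure sources surgical images add: soft tissue around the
distal fragments and fragment overlap in the lateral view. Passing the
shipped bounds under these profiles shows the pipeline tolerates this
noise *structure* at this *scale*; it does not certify performance on real
radiographs, whose artefacts (scatter, beam hardening, soft-tissue
gradients) are richer than additive noise on clean silhouettes.

### The end-to-end experiment

`run_experiment()` replays the whole protocol per seed: generate the scene,
render and calibrate a grid image (the estimated pixel size — not the
configured one — parameterises all later stages), then per fragment render
both views, detect and jitter features, estimate view poses, segment
contours from the manual-alignment projection, perturb them with contour
noise and occlusion, coarse-align and register, and score sTRE against the
generator's ground truth. Measured contours are denoised with a circular
Savitzky–Golay filter (local quadratic, window 9: unlike a moving average
it does not shrink curved regions) before registration. Registration runs
in two passes — the contours are re-segmented at the first registered pose,
whose projection matches the imaged contour far better than the manual one
— and a multi-start guard restarts from the manual pose when the fit from
the coarse init is implausibly poor for the profile's noise level (the
alternating correspondence/Gauss–Newton scheme has init-dependent local
minima). The surgeon's manual alignment is modelled by
what the surgeon actually verifies on screen: a seeded perturbation
(up to ±5° rotation, ±8 mm depth, ±2 mm in-plane) accepted only when the
projected contour stays within 12 px of the true one in both views, with
the perturbation shrunk until it does.

## Numerical choices and degenerate inputs

* P3P quartic roots are accepted with a loose imaginary tolerance and
  polished by Newton iteration (double roots lose half their precision in
  any quartic solver); candidates with non-positive depths are discarded.
* Contour splines are periodic interpolating cubics through up to 200
  knots, resampled to 600 dense points for closest-point queries; the
  optional circular moving-average smoother is capped at 0.5 px
  displacement so knots remain faithful to the measured edge. Smoothing is
  off for clean segmentations (it biases curved regions inward) and
  enabled (half-width 1–2) when contour noise is expected.
* Ties in coarse alignment resolve to the first-drawn candidate; the
  search is reproducible because every random draw in the package flows
  through a seed argument and restores the caller's RNG state.
* Degenerate cuts (a fragment under 1000 mm³) trigger plane adjustment and
  regeneration, with a message.
* Meshes are re-oriented by breadth-first winding propagation plus a
  global volume-sign check, so builders need not get triangle orientation
  right everywhere.

## Problem sizes

The shipped test suite and the acceptance script run the experiments at
the package's declared study conditions: 20 seeds per noise profile, 5
seeds for the zero-noise fixed-point check, n = 100 sTRE points, 200
contour samples per view, 150 registration silhouette samples per view,
and a 36-sample, 3-round coarse search (plus pattern probes and the
Gauss-Newton polish) around the manual alignment. Property suites use reduced replication (8 seeds per
contour-noise level, 50 per detection-noise level) — enough to order
medians — and the pose-grid oracle uses a 2.5 mm / 2.5° step over the
±5 mm / ±5° box.

## Known limitations

* The renderer is geometric, not radiometric; intensity-based (DRR
  similarity) registration cannot be prototyped against it.
* Single-view registration is supported but depth-ambiguous by geometry;
  the two-view protocol is the intended use.
* The fiducial must be fully inside both fields of view; the renderer
  refuses scenes that do not fit rather than cropping.
* Occlusion handling drops contour evidence; it does not attempt to
  disentangle overlapping fragments in the image.
* The pin-to-fragment transform is treated as exact after registration;
  pin bending or migration during manipulation is out of scope.
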