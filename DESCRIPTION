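Package: fluororeg
Title: Fiducial-Based 2D/3D Registration of Bone Fragments to C-Arm Fluoroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for intra-operative registration of CT-derived bone-fragment
    meshes to two calibrated fluoroscopic views, as used in image-guided
    fracture-reduction surgery. Implements C-arm distortion correction and
    pixel-size estimation from a ball-bearing grid phantom, 6-DOF view pose
    estimation from a four-point fiducial (three radiopaque beads plus a pin
    tip) by perspective-n-point, silhouette-to-contour rigid registration of
    triangle meshes by damped Gauss-Newton minimisation, surface target
    registration error (sTRE) evaluation on labelled fracture surfaces, and a
    synthetic radiographic phantom generator producing fractured distal-femur
    meshes and two-view renders with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    grDevices,
    utils,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    tiff,
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
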