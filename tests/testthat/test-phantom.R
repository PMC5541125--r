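test_that("generated fragments are watertight, labelled and conserve volume", {
  for (type in c("Y", "T")) {
    sc <- generate_phantom(phantom_spec(type, seed = 3))
    expect_named(sc$fragments, c("FEM", "F1", "F2"))
    vols <- vapply(sc$fragments, function(f) mesh_volume(f$mesh), 1)
    expect_true(all(vols > 1000))
    for (f in sc$fragments) {
      expect_true(mesh_is_watertight(f$mesh))
      expect_gt(sum(mesh_face_areas(f$mesh)[f$mesh$fracture]), 0)
    }
    expect_lt(abs(sum(vols) - sc$full_volume) / sc$full_volume, 0.005)
  }
})

test_that("phantom generation and STL export are deterministic", {
  a <- generate_phantom(phantom_spec("Y", seed = 11))
  b <- generate_phantom(phantom_spec("Y", seed = 11))
  expect_identical(a$fragments$F1$mesh$v, b$fragments$F1$mesh$v)
  expect_identical(rt_matrix(a$fragments$F2$pin_pose),
                   rt_matrix(b$fragments$F2$pin_pose))
  p1 <- withr::local_tempfile(fileext = ".stl")
  p2 <- withr::local_tempfile(fileext = ".stl")
  write_mesh(a$fragments$F1$mesh, p1)
  write_mesh(b$fragments$F1$mesh, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("CT-voxel quantisation moves vertices by less than a voxel diagonal", {
  q <- generate_phantom(phantom_spec("Y", seed = 3, quantise = TRUE))
  u <- generate_phantom(phantom_spec("Y", seed = 3, quantise = FALSE))
  d <- sqrt(rowSums((q$fragments$F1$mesh$v - u$fragments$F1$mesh$v)^2))
  expect_lt(max(d), sqrt(sum(c(0.58, 0.58, 0.75)^2)))
  expect_true(mesh_is_watertight(q$fragments$F1$mesh))
})

test_that("rendering is deterministic and ground truth reprojects exactly", {
  sc <- test_scene(0)
  carm <- carm_default()
  prof <- noise_profile(pixel_noise = 0.01)
  r1 <- render_view(sc, "F2", carm, 90, prof, seed = 4)
  r2 <- render_view(sc, "F2", carm, 90, prof, seed = 4)
  expect_identical(r1$image, r2$image)
  r3 <- render_view(sc, "F2", carm, 90, prof, seed = 5)
  expect_false(identical(r3$image, r1$image))
  # stored features equal direct projection of the fiducial through the
  # stored camera pose
  feats <- project_points(carm, r1$truth$camera_pose,
                          fiducial_points(sc$fid), distort = FALSE)
  expect_lt(max(abs(feats - r1$truth$features)), 1e-6)
  # AP and LAT camera poses differ by exactly the 30-degree orbit
  lat <- render_view(sc, "F2", carm, 60, prof, seed = 4)
  rel <- rt_compose(r1$truth$camera_pose, rt_invert(lat$truth$camera_pose))
  expect_equal(rotation_angle_deg(rel$R), 30, tolerance = 1e-9)
})

test_that("calibration grid renders at the closed-form pitch", {
  carm <- carm_default()
  grid <- bead_grid_model()
  ci <- render_calibration_image(carm, grid, seed = 2)
  ci2 <- render_calibration_image(carm, grid, seed = 2)
  expect_identical(ci$image, ci2$image)
  # 22 mm / 0.224 mm/px = 98.2143 px pitch at unit magnification
  lat <- ci$truth$ideal
  du <- diff(sort(unique(round(lat[, 1], 6))))
  expect_equal(mean(du), 22 / 0.224, tolerance = 1e-6)
  # segmentation + matching on the rendered image is sub-0.05 px
  cc <- match_grid(segment_beads(ci$image, 49), grid, carm)
  expect_lt(max(sqrt((cc$det_u - cc$ideal_u)^2 + (cc$det_v - cc$ideal_v)^2)),
            0.05)
})

test_that("a render with distortion bends the recorded bead lattice", {
  carm <- carm_model(distortion = default_distortion())
  grid <- bead_grid_model()
  ci <- render_calibration_image(carm, grid, seed = 2)
  shift <- sqrt(rowSums((ci$truth$rendered - ci$truth$ideal)^2))
  expect_gt(max(shift), 0.8)         # periphery visibly stretched
  expect_lt(min(shift), 0.2)         # centre nearly untouched
  cal <- calibrate_carm(ci$image, grid, carm_model())
  # learned correction undoes the synthetic distortion on the bead lattice
  fixed <- correct_points(cal$correction, ci$truth$rendered)
  expect_lt(sqrt(mean(rowSums((fixed - ci$truth$ideal)^2))), 0.1)
})
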