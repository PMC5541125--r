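carm <- carm_model()
fid <- fiducial_default()

synth_detections <- function(pose, jitter = 0, seed = NULL) {
  px <- project_points(carm, pose, fiducial_points(fid), distort = FALSE)
  if (jitter > 0) {
    if (!is.null(seed)) set.seed(seed)
    px <- px + matrix(rnorm(8, 0, jitter), 4, 2)
  }
  feature_detections(px)
}

test_that("fiducial geometry invariants are enforced", {
  expect_error(fiducial_geometry(rbind(c(0, 0, 10), c(10, 0, 10), c(5, 5, 10)),
                                 c(5, 2, 10)), "coplanar")
  expect_error(fiducial_geometry(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0)),
                                 c(0, 0, 10)), "distinct")
  expect_s3_class(fid, "fiducial_geometry")
})

test_that("perspective-4-point recovers exact poses", {
  pose0 <- rigid_transform(diag(3), c(0, 0, 600))
  ip <- estimate_image_pose(synth_detections(pose0), fid, carm)
  expect_pose_close(ip$pose, pose0, 0.01, 0.01)
  expect_lt(ip$rms_reprojection, 1e-6)
  set.seed(11)
  for (i in 1:100) {
    pose <- rigid_transform(rot_from_vec(rnorm(3) * 0.5),
                            c(runif(2, -20, 20), runif(1, 600, 800)))
    ip <- estimate_image_pose(synth_detections(pose), fid, carm)
    expect_pose_close(ip$pose, pose, 0.05, 0.05)
    expect_lt(ip$rms_reprojection, 1e-3)
  }
})

test_that("stored reprojection RMS is reproducible from the pose", {
  set.seed(21)
  pose <- rigid_transform(rot_from_vec(rnorm(3) * 0.3), c(5, -8, 700))
  det <- synth_detections(pose, jitter = 0.5, seed = 2)
  ip <- estimate_image_pose(det, fid, carm)
  px <- project_points(carm, ip$pose, fiducial_points(fid), distort = FALSE)
  rms <- sqrt(mean(rowSums((px - det$points)^2)))
  expect_equal(ip$rms_reprojection, rms, tolerance = 1e-9)
  expect_equal(ip$per_point_residuals, sqrt(rowSums((px - det$points)^2)),
               tolerance = 1e-9)
})

test_that("refined pose beats every point of a coarse 6-DOF grid", {
  set.seed(31)
  pose <- rigid_transform(rot_from_vec(rnorm(3) * 0.3), c(3, 4, 700))
  det <- synth_detections(pose, jitter = 0.3, seed = 5)
  ip <- estimate_image_pose(det, fid, carm)
  X <- fiducial_points(fid)
  steps <- c(-5, -2.5, 0, 2.5, 5)
  best_grid <- Inf
  for (dx in steps) for (dy in steps) for (dz in steps) {
    for (wx in steps) for (wy in steps) for (wz in steps) {
      cand <- rt_update(pose, c(c(wx, wy, wz) * pi / 180, dx, dy, dz))
      pc <- rt_apply(cand, X)
      if (any(pc[, 3] <= 0)) next
      px <- project_points(carm, cand, X, distort = FALSE)
      best_grid <- min(best_grid, sqrt(mean(rowSums((px - det$points)^2))))
    }
  }
  expect_lte(ip$rms_reprojection, best_grid)
})

test_that("pose error grows monotonically with detection noise", {
  sigmas <- c(0, 0.25, 0.5, 1.0)
  med_err <- vapply(sigmas, function(s) {
    errs <- vapply(1:50, function(k) {
      set.seed(k)
      pose <- rigid_transform(rot_from_vec(rnorm(3) * 0.4),
                              c(runif(2, -15, 15), runif(1, 650, 800)))
      ip <- estimate_image_pose(synth_detections(pose, s, seed = 1000 + k),
                                fid, carm)
      rt_distance(ip$pose, pose)[["trans"]]
    }, 1)
    median(errs)
  }, 1)
  expect_true(all(diff(med_err) >= 0))
})

test_that("automated detection finds the fiducial to sub-0.1 px when clean", {
  r <- test_render(0, "F1", 90)
  det <- detect_features(r$image, carm, test_scene(0)$fid)
  err <- sqrt(rowSums((det$points - r$truth$features)^2))
  expect_lt(max(err), 0.1)
  # blurred/noisy image still localises well
  rn <- test_render(0, "F1", 90, noise_profile(pixel_noise = 0.02,
                                               blur_sigma_px = 1), 5)
  detn <- detect_features(rn$image, carm, test_scene(0)$fid)
  errn <- sqrt(rowSums((detn$points - rn$truth$features)^2))
  expect_lt(mean(errn), 0.5)
  # featureless image errors out
  expect_error(detect_features(matrix(0.05, 300, 300), carm, test_scene(0)$fid),
               "detection error")
})

test_that("AP and LAT estimated view poses differ by the 30-degree orbit", {
  sc <- test_scene(0)
  ap <- test_render(0, "F1", 90)
  lat <- test_render(0, "F1", 60)
  ip_ap <- estimate_image_pose(detect_features(ap$image, carm, sc$fid),
                               sc$fid, carm)
  ip_lat <- estimate_image_pose(detect_features(lat$image, carm, sc$fid),
                                sc$fid, carm)
  rel <- rt_compose(ip_ap$pose, rt_invert(ip_lat$pose))
  expect_equal(rotation_angle_deg(rel$R), 30, tolerance = 0.1)
})
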