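carm <- carm_model()

test_that("contour2d splines stay near their knots and validate input", {
  th <- seq(0, 2 * pi, length.out = 41)[-41]
  pts <- cbind(500 + 100 * cos(th), 500 + 80 * sin(th))
  ct <- contour2d(pts, smooth = 1)
  d <- sqrt(rowSums((ct$points - pts)^2))
  expect_lt(max(d), 0.5 + 1e-9)   # smoothing displacement is capped at 0.5 px
  expect_error(contour2d(pts[1:4, ]), "at least 8")
  # closest-point distances: a point at the ellipse centre is ~80 px away
  expect_equal(as.numeric(contour_distance(ct, c(500, 500))), 80,
               tolerance = 0.5)
})

test_that("sphere silhouette projects to a circle of the analytic radius", {
  sph <- uv_sphere(20, n_phi = 64, n_theta = 48)
  pose <- rigid_transform(diag(3), c(0, 0, 490))
  ct <- extract_silhouette(sph, carm, rt_identity(), pose)
  r_px <- sqrt(rowSums(sweep(ct$dense, 2, carm$principal_point)^2))
  r_true <- (20 * 980 / 490) / 0.224
  expect_lt(abs(mean(r_px) - r_true) / r_true, 0.01)
  expect_lt(diff(range(r_px)), 1.5)
})

test_that("face-on box silhouette is the analytic rectangle", {
  box <- box_mesh(30, 20, 10)
  z0 <- 600
  pose <- rigid_transform(diag(3), c(0, 0, z0))
  ct <- extract_silhouette(box, carm, rt_identity(), pose)
  pp <- carm$principal_point
  # near face at z0 - 5 dominates the silhouette
  zn <- z0 - 5
  half_u <- (15 * 980 / zn) / 0.224
  half_v <- (10 * 980 / zn) / 0.224
  expect_equal(max(ct$dense[, 1]) - pp[1], half_u, tolerance = 0.5)
  expect_equal(pp[1] - min(ct$dense[, 1]), half_u, tolerance = 0.5)
  expect_equal(max(ct$dense[, 2]) - pp[2], half_v, tolerance = 0.5)
  # in-plane translation of the pose translates the silhouette
  pose2 <- rigid_transform(diag(3), c(6, -4, z0))
  ct2 <- extract_silhouette(box, carm, rt_identity(), pose2)
  shift_u <- (6 * 980 / zn) / 0.224
  expect_equal(max(ct2$dense[, 1]) - max(ct$dense[, 1]), shift_u,
               tolerance = 0.5)
  # mesh behind the source errors
  expect_error(extract_silhouette(box, carm, rt_identity(),
                                  rigid_transform(diag(3), c(0, 0, -400))),
               "behind")
})

test_that("contour refinement locks onto the rendered bone edge", {
  sc <- test_scene(0)
  fr <- sc$fragments$F1
  r <- test_render(0, "F1", 90)
  truth_ct <- r$truth$silhouette
  # init at the true silhouette: refinement stays within 0.3 px RMS
  seg <- segment_contour(r$image, truth_ct)
  d <- contour_distance(truth_ct, seg$points)
  expect_lt(sqrt(mean(d^2)), 0.3)
  # init shifted 5 px outward still recovers the edge
  ctr <- colMeans(truth_ct$points)
  off <- truth_ct$points +
    5 * sweep(truth_ct$points, 2, ctr) /
    sqrt(rowSums(sweep(truth_ct$points, 2, ctr)^2))
  seg2 <- segment_contour(r$image, contour2d(off))
  d2 <- contour_distance(truth_ct, seg2$points)
  expect_lt(sqrt(mean(d2^2)), 0.5)
  # forcing 70% of the samples occluded raises the failure error
  mask <- rep(FALSE, 200); mask[1:140] <- TRUE
  expect_error(segment_contour(r$image, truth_ct,
                               params = list(occluded_mask = mask)),
               "segmentation failure")
})

test_that("occluded spans are bridged but flagged unsupported", {
  sc <- test_scene(0)
  r <- test_render(0, "F1", 90)
  mask <- rep(FALSE, 200); mask[30:69] <- TRUE   # 20% contiguous occlusion
  seg <- segment_contour(r$image, r$truth$silhouette,
                         params = list(occluded_mask = mask))
  expect_lt(attr(seg, "kept_frac"), 0.85)
  d <- contour_distance(seg, r$truth$silhouette$points)
  expect_true(any(!attr(d, "support")))
  expect_true(mean(attr(d, "support")) > 0.5)
})
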