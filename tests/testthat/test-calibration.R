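carm <- carm_model()
grid <- bead_grid_model()        # 22 mm pitch, 10 mm beads, 7 x 7

test_that("bead segmentation recovers rendered centroids", {
  ci <- memo("calib_clean", render_calibration_image(carm, grid, seed = 1))
  cents <- segment_beads(ci$image, 49)
  expect_equal(nrow(cents), 49L)
  # match each detection to its rendered truth
  d <- sqrt(outer(cents[, 1], ci$truth$rendered[, 1], "-")^2 +
            outer(cents[, 2], ci$truth$rendered[, 2], "-")^2)
  expect_lt(max(apply(d, 1, min)), 0.05)
  # blank image reports a coverage error
  expect_error(segment_beads(matrix(0.1, 200, 200), 49), "coverage")
  # noisy grid still yields all beads at sub-pixel accuracy
  cn <- render_calibration_image(carm, grid, seed = 7, pixel_noise = 0.02)
  cents_n <- segment_beads(cn$image, 49)
  dn <- sqrt(outer(cents_n[, 1], cn$truth$rendered[, 1], "-")^2 +
             outer(cents_n[, 2], cn$truth$rendered[, 2], "-")^2)
  expect_lt(mean(apply(dn, 1, min)), 0.3)
})

test_that("grid matching is bijective and survives in-plane rotation", {
  ci <- memo("calib_clean", render_calibration_image(carm, grid, seed = 1))
  cents <- segment_beads(ci$image, 49)
  cc <- match_grid(cents, grid, carm)
  expect_equal(nrow(cc), 49L)
  expect_lt(max(sqrt((cc$det_u - cc$ideal_u)^2 + (cc$det_v - cc$ideal_v)^2)),
            0.1)
  expect_false(anyDuplicated(paste(cc$row, cc$col)) > 0)
  # rotate the detected lattice 5 degrees about the centre: same matching
  ctr <- colMeans(cents)
  ang <- 5 * pi / 180
  Rm <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  rot <- sweep(sweep(cents, 2, ctr) %*% t(Rm), 2, ctr, "+")
  cc_rot <- match_grid(rot, grid, carm)
  expect_equal(cc_rot[order(cc_rot$row, cc_rot$col), c("row", "col")],
               cc[order(cc$row, cc$col), c("row", "col")])
  # a duplicated centroid makes the assignment ambiguous
  expect_error(match_grid(rbind(cents, cents[1, ] + 0.5), grid, carm),
               "ambiguous")
})

test_that("polynomial correction fits the shipped intensifier distortion", {
  lat <- fluororeg:::grid_lattice_px(grid, carm)
  cols <- rep(seq_len(7), times = 7); rows <- rep(seq_len(7), each = 7)
  dist <- default_distortion(carm)
  det <- apply_distortion(dist, lat)
  cc <- data.frame(det_u = det[, 1], det_v = det[, 2],
                   ideal_u = lat[, 1], ideal_v = lat[, 2],
                   row = rows, col = cols)
  # identity correspondences: correction is the identity map
  cc_id <- cc; cc_id$det_u <- cc$ideal_u; cc_id$det_v <- cc$ideal_v
  corr_id <- fit_distortion(cc_id, degree = 3)
  expect_lt(corr_id$fit_rms, 1e-6)
  # fit on the interior 5x5, validate on the border ring
  interior <- cc$row %in% 2:6 & cc$col %in% 2:6
  corr3 <- fit_distortion(cc[interior, ], degree = 3)
  pred <- correct_points(corr3, det[!interior, , drop = FALSE])
  rms3 <- sqrt(mean((pred[, 1] - lat[!interior, 1])^2 +
                    (pred[, 2] - lat[!interior, 2])^2))
  expect_lt(rms3, 0.1)
  expect_error(fit_distortion(cc[1:5, ], degree = 3), "fit error")
})

test_that("model capacity orders hold-out error under strong distortion", {
  lat <- fluororeg:::grid_lattice_px(grid, carm)
  cols <- rep(seq_len(7), times = 7); rows <- rep(seq_len(7), each = 7)
  det <- apply_distortion(radial_distortion(5e-7, carm$principal_point), lat)
  cc <- data.frame(det_u = det[, 1], det_v = det[, 2],
                   ideal_u = lat[, 1], ideal_v = lat[, 2],
                   row = rows, col = cols)
  interior <- cc$row %in% 2:6 & cc$col %in% 2:6
  rms_at <- function(deg) {
    corr <- fit_distortion(cc[interior, ], degree = deg)
    pred <- correct_points(corr, det[!interior, , drop = FALSE])
    sqrt(mean((pred[, 1] - lat[!interior, 1])^2 +
              (pred[, 2] - lat[!interior, 2])^2))
  }
  expect_gt(rms_at(2), rms_at(3))
})

test_that("distortion round trip corrects a dense test lattice", {
  dist <- default_distortion(carm)
  lat <- fluororeg:::grid_lattice_px(grid, carm)
  cc <- data.frame(det_u = apply_distortion(dist, lat)[, 1],
                   det_v = apply_distortion(dist, lat)[, 2],
                   ideal_u = lat[, 1], ideal_v = lat[, 2])
  corr <- fit_distortion(cc, degree = 3)
  us <- seq(min(lat[, 1]), max(lat[, 1]), length.out = 15)
  dense <- as.matrix(expand.grid(us, us))
  fixed <- correct_points(corr, apply_distortion(dist, dense))
  expect_lt(sqrt(mean(rowSums((fixed - dense)^2))), 0.1)
})

test_that("pixel size is estimated from the detected lattice pitch", {
  ci <- memo("calib_clean", render_calibration_image(carm, grid, seed = 1))
  cc <- match_grid(segment_beads(ci$image, 49), grid, carm)
  ps <- estimate_pixel_size(cc, grid)
  expect_equal(ps, 0.224, tolerance = 1e-3)
  # pitch doubled -> estimate halves (inverse proportionality)
  cc2 <- cc
  pp <- carm$principal_point
  cc2$det_u <- pp[1] + 2 * (cc$det_u - pp[1])
  cc2$det_v <- pp[2] + 2 * (cc$det_v - pp[2])
  expect_equal(estimate_pixel_size(cc2, grid), ps / 2, tolerance = 1e-6)
  # unbiased under zero-mean centroid noise: mean over 50 seeds
  est <- vapply(1:50, function(s) {
    set.seed(s)
    ccn <- cc
    ccn$det_u <- cc$det_u + rnorm(49, 0, 0.3)
    ccn$det_v <- cc$det_v + rnorm(49, 0, 0.3)
    estimate_pixel_size(ccn, grid)
  }, 1)
  expect_lt(abs(mean(est) - 0.224) / 0.224, 0.002)
  expect_lt(abs(est[3] - 0.224) / 0.224, 0.005)  # single noisy grid within 0.5%
})

test_that("full calibration recovers an undistorted default grid exactly", {
  ci <- memo("calib_clean", render_calibration_image(carm, grid, seed = 1))
  cal <- calibrate_carm(ci$image, grid, carm)
  expect_equal(cal$pixel_size_estimate, 0.224, tolerance = 1e-3)
  expect_lt(cal$correction$fit_rms, 0.1)
  expect_lt(cal$holdout_rms, 0.2)
  # correction fitted to an undistorted grid is the identity map
  test_pts <- cbind(runif(50, 200, 800), runif(50, 200, 800))
  moved <- correct_points(cal$correction, test_pts)
  expect_lt(max(sqrt(rowSums((moved - test_pts)^2))), 0.2)
})
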