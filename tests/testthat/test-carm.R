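test_that("pinhole projection matches hand-evaluated cases", {
  carm <- carm_model()  # SID 980, 0.224 mm/px, 230 mm intensifier
  pp <- carm$principal_point
  # optical-axis point lands on the principal point
  expect_equal(as.numeric(project_points(carm, rt_identity(), c(0, 0, 490))),
               pp, tolerance = 1e-12)
  # lateral 10 mm at 490 mm: (10 * 980 / 490) / 0.224 = 89.2857 px
  p <- project_points(carm, rt_identity(), c(10, 0, 490))
  expect_equal(p[1, 1] - pp[1], (10 * 980 / 490) / 0.224, tolerance = 1e-9)
  expect_equal(p[1, 2], pp[2])
  # detector-plane point: unit magnification
  q <- project_points(carm, rt_identity(), c(7, -3, 980))
  expect_equal(q[1, 1] - pp[1], 7 / 0.224, tolerance = 1e-9)
  expect_equal(q[1, 2] - pp[2], -3 / 0.224, tolerance = 1e-9)
  # behind the source is invalid
  expect_error(project_points(carm, rt_identity(), c(0, 0, -5)),
               "behind the X-ray source")
})

test_that("projection is linear in lateral offset (magnification)", {
  carm <- carm_model()
  pp <- carm$principal_point
  z <- 700
  p1 <- project_points(carm, rt_identity(), c(5, 0, z))[1, 1] - pp[1]
  p2 <- project_points(carm, rt_identity(), c(20, 0, z))[1, 1] - pp[1]
  expect_equal(p2 / p1, 4, tolerance = 1e-9)
})

test_that("radial distortion follows the polynomial and its symmetries", {
  ctr <- c(500, 500)
  d0 <- radial_distortion(c(0, 0), ctr)
  pts <- cbind(runif(10, 100, 900), runif(10, 100, 900))
  expect_equal(apply_distortion(d0, pts), unname(pts))
  d1 <- radial_distortion(1e-6, ctr)
  expect_equal(apply_distortion(d1, rbind(ctr)), rbind(ctr))
  # k1 = 1e-6 px^-2 at r = 100: r' = 100 * (1 + 1e-6 * 1e4) = 101
  out <- apply_distortion(d1, rbind(ctr + c(100, 0)))
  expect_equal(out[1, 1] - ctr[1], 101, tolerance = 1e-9)
  # radial symmetry: rotating inputs about the centre rotates outputs
  set.seed(5)
  ang <- runif(1, 0, 2 * pi)
  Rm <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  x <- cbind(runif(20, -300, 300), runif(20, -300, 300))
  a <- apply_distortion(d1, sweep(x %*% t(Rm), 2, ctr, "+"))
  b <- sweep(apply_distortion(d1, sweep(x, 2, ctr, "+")), 2, ctr) %*% t(Rm)
  expect_lt(max(abs(sweep(a, 2, ctr) - b)), 1e-9)
})

test_that("orbit camera poses differ by the orbit rotation", {
  ctr <- c(5, -3, 10)
  ap <- orbit_camera_pose(ctr, 800, 90)
  lat <- orbit_camera_pose(ctr, 800, 60)
  rel <- rt_compose(ap, rt_invert(lat))
  expect_equal(rotation_angle_deg(rel$R), 30, tolerance = 1e-9)
  # the orbit axis (world z) is the rotation axis
  ax <- rot_to_vec(t(ap$R) %*% rel$R %*% ap$R)
  expect_equal(abs(ax[3]) / sqrt(sum(ax^2)), 1, tolerance = 1e-9)
})
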