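test_that("fracture-surface sampling is area-uniform and deterministic", {
  sc <- test_scene(0)
  mesh <- sc$fragments$F1$mesh
  s1 <- sample_fracture_surface(mesh, 100, seed = 0)
  s2 <- sample_fracture_surface(mesh, 100, seed = 0)
  expect_identical(s1$points, s2$points)
  expect_equal(sample_fracture_surface(mesh, 0)$n, 0L)
  m2 <- mesh; m2$fracture[] <- FALSE
  expect_error(sample_fracture_surface(m2, 10), "labelling error")
  # single labelled triangle: points stay inside, centroid converges
  tri <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                  rbind(c(1, 2, 3), c(1, 4, 2), c(2, 4, 3), c(1, 3, 4)),
                  c(TRUE, FALSE, FALSE, FALSE))
  st <- sample_fracture_surface(tri, 1000, seed = 1)
  expect_true(all(st$points[, 3] == 0))
  expect_true(all(st$points[, 1] >= 0 & st$points[, 2] >= 0 &
                  st$points[, 1] + st$points[, 2] <= 1 + 1e-12))
  expect_lt(max(abs(colMeans(st$points) - c(1 / 3, 1 / 3, 0))), 0.05)
})

test_that("sTRE matches hand-computed displacements", {
  sc <- test_scene(0)
  samp <- sample_fracture_surface(sc$fragments$F1$mesh, 200, seed = 3)
  pose <- sc$fragments$F1$pose_world
  expect_equal(compute_stre(samp, pose, pose)$mean, 0)
  shifted <- rigid_transform(pose$R, pose$t + c(1, 0, 0))
  rep1 <- compute_stre(samp, pose, shifted)
  expect_equal(rep1$mean, 1, tolerance = 1e-12)
  expect_equal(rep1$sd, 0, tolerance = 1e-12)
  # 1-degree rotation about an axis through the sample centroid: per-point
  # oracle computed directly
  ctr <- colMeans(samp$points)
  R1 <- rot_from_vec(c(0, 0, 1) * pi / 180)
  rot_about_ctr <- rt_compose(pose,
    rigid_transform(R1, as.numeric(ctr - R1 %*% ctr)))
  rep2 <- compute_stre(samp, pose, rot_about_ctr)
  oracle <- sqrt(rowSums((sweep(samp$points, 2, ctr) %*% t(R1) -
                          sweep(samp$points, 2, ctr))^2))
  expect_equal(rep2$per_point, oracle, tolerance = 1e-9)
  expect_equal(rep2$mean, mean(oracle), tolerance = 1e-12)
})

test_that("sTRE is invariant under a common rigid transform and bounded", {
  sc <- test_scene(0)
  samp <- sample_fracture_surface(sc$fragments$F2$mesh, 150, seed = 5)
  pose <- sc$fragments$F2$pose_world
  set.seed(8)
  est <- rt_update(pose, c(rnorm(3) * 0.01, rnorm(3) * 0.5))
  g <- rt_random_seeded(99)
  a <- compute_stre(samp, pose, est)
  b <- compute_stre(samp, rt_compose(g, pose), rt_compose(g, est))
  expect_equal(a$per_point, b$per_point, tolerance = 1e-9)
  # triangle-inequality upper bound for translation + rotation about centroid
  ctr <- colMeans(samp$points)
  th <- 2 * pi / 180; tvec <- c(0.5, -0.3, 0.2)
  R <- rot_from_vec(c(0, 1, 0) * th)
  est2 <- rt_compose(pose, rigid_transform(R, as.numeric(ctr - R %*% ctr) + tvec))
  rep3 <- compute_stre(samp, pose, est2)
  rmax <- max(sqrt(rowSums(sweep(samp$points, 2, ctr)^2)))
  bound <- sqrt(sum(tvec^2)) + 2 * sin(th / 2) * rmax
  expect_lte(rep3$mean, bound + 1e-9)
})

test_that("robot target poses follow the registration chain exactly", {
  d0 <- desired_pose(rt_random_seeded(61))
  expect_equal(rt_matrix(rfm_target_pose(rt_identity(), rt_identity(), d0)$pose),
               rt_matrix(d0$pose))
  set.seed(6)
  for (i in 1:10) {
    a <- rt_random(); b <- rt_random(); d <- desired_pose(rt_random())
    out <- rfm_target_pose(a, b, d)
    oracle <- rt_matrix(a) %*% rt_matrix(b) %*% rt_matrix(d$pose)
    expect_lt(max(abs(rt_matrix(out$pose) - oracle)), 1e-9)
    # grouping either way is identical (associativity)
    alt <- rt_compose(rt_compose(a, b), d$pose)
    expect_lt(max(abs(rt_matrix(out$pose) - rt_matrix(alt))), 1e-9)
    # composition order matters: the reversed order differs
    swapped <- rt_matrix(b) %*% rt_matrix(a) %*% rt_matrix(d$pose)
    expect_gt(max(abs(rt_matrix(out$pose) - swapped)), 1e-6)
  }
})

test_that("reduction RMSE matches hand-computed values", {
  P <- rbind(c(10, 0, 0), c(0, 10, 0), c(0, 0, 10))
  des <- list(rt_identity(), rt_identity(), rt_identity(), rt_identity())
  ach0 <- des
  expect_equal(reduction_rmse(ach0, des, P),
               c(trans_mm = 0, rot_deg = 0))
  offs <- c(1, 2, 2, 3)
  ach <- lapply(offs, function(o) rigid_transform(diag(3), c(o, 0, 0)))
  out <- reduction_rmse(ach, des, P)
  expect_equal(out[["trans_mm"]], sqrt(mean(offs^2)), tolerance = 1e-12)
  expect_equal(out[["trans_mm"]], 2.1213, tolerance = 1e-4)
  ach2 <- lapply(offs, function(o) rigid_transform(diag(3), c(2, 0, 0)))
  expect_equal(reduction_rmse(ach2, des, P)[["trans_mm"]], 2)
  expect_error(reduction_rmse(ach[1:2], des, P), "length")
})
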