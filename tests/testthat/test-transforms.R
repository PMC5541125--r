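test_that("compose and invert match the homogeneous 4x4 matrix oracle", {
  expect_equal(rt_matrix(rt_compose(rt_random_seeded(10), rt_identity())),
               rt_matrix(rt_random_seeded(10)))
  set.seed(0)
  for (i in 1:20) {
    a <- rt_random(); b <- rt_random()
    expect_equal(rt_matrix(rt_compose(a, b)), rt_matrix(a) %*% rt_matrix(b),
                 tolerance = 1e-12)
  }
  set.seed(1)
  for (i in 1:20) {
    t <- rt_random()
    expect_lt(max(abs(rt_matrix(rt_invert(t)) - solve(rt_matrix(t)))), 1e-9)
    expect_lt(max(abs(rt_matrix(rt_compose(t, rt_invert(t))) - diag(4))), 1e-9)
  }
  # pure translation inverts by sign
  tr <- rigid_transform(diag(3), c(1, 2, 3))
  expect_equal(rt_invert(tr)$t, c(-1, -2, -3))
})

test_that("transform group laws hold on random transforms", {
  set.seed(42)
  for (i in 1:100) {
    a <- rt_random(); b <- rt_random(); c3 <- rt_random()
    lhs <- rt_compose(rt_compose(a, b), c3)
    rhs <- rt_compose(a, rt_compose(b, c3))
    expect_lt(max(abs(rt_matrix(lhs) - rt_matrix(rhs))), 1e-9)
    x <- rnorm(3) * 50
    expect_equal(rt_apply(a, rt_apply(b, x)), rt_apply(rt_compose(a, b), x),
                 tolerance = 1e-9)
  }
})

test_that("rotation vector round trip and geodesic angle behave", {
  set.seed(3)
  for (i in 1:50) {
    w <- rnorm(3) * runif(1, 0, 3)
    R <- rot_from_vec(w)
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-12)
    expect_equal(rot_from_vec(rot_to_vec(R)), R, tolerance = 1e-8)
  }
  expect_equal(rotation_angle_deg(rot_from_vec(c(0, 0, pi / 6))), 30,
               tolerance = 1e-10)
})

test_that("invalid rotations are rejected", {
  m <- diag(4); m[1, 1] <- 1.01
  expect_error(rt_from_matrix(m), "orthonormality")
  expect_error(rigid_transform(matrix(rnorm(9), 3, 3), c(0, 0, 0)),
               "orthonormal")
})
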