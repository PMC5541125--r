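# shared fixtures, built in code and memoised for the session

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

test_scene <- function(seed = 0, type = "Y") {
  memo(paste0("scene_", type, seed),
       generate_phantom(phantom_spec(type, seed = seed)))
}

test_render <- function(seed = 0, fragment = "F1", angle = 90,
                        profile = noise_profile(), noise_seed = 1) {
  key <- paste0("render_", seed, fragment, angle, noise_seed,
                profile$pixel_noise)
  memo(key, render_view(test_scene(seed), fragment, carm_default(), angle,
                        noise = profile, seed = noise_seed))
}

# UV-sphere triangle mesh (for analytic silhouette checks)
uv_sphere <- function(radius = 20, n_phi = 48, n_theta = 32) {
  th <- seq(0, pi, length.out = n_theta + 1L)
  phi <- seq(0, 2 * pi, length.out = n_phi + 1L)[-(n_phi + 1L)]
  rows <- lapply(th[-c(1, n_theta + 1L)], function(t)
    cbind(radius * sin(t) * cos(phi), radius * sin(t) * sin(phi),
          radius * cos(t)))
  v <- rbind(c(0, 0, radius), do.call(rbind, rows), c(0, 0, -radius))
  nr <- length(rows)
  idx <- function(i, j) 1L + (i - 1L) * n_phi + ((j - 1L) %% n_phi) + 0L
  f <- list()
  for (j in seq_len(n_phi)) {
    f[[length(f) + 1L]] <- c(1L, idx(1, j), idx(1, j + 1))
    f[[length(f) + 1L]] <- c(nrow(v), idx(nr, j + 1), idx(nr, j))
  }
  for (i in seq_len(nr - 1L)) for (j in seq_len(n_phi)) {
    a <- idx(i, j); b <- idx(i, j + 1); c2 <- idx(i + 1, j + 1); d <- idx(i + 1, j)
    f[[length(f) + 1L]] <- c(a, b, c2)
    f[[length(f) + 1L]] <- c(a, c2, d)
  }
  m <- tri_mesh(v, do.call(rbind, f))
  if (mesh_volume(m) < 0) m$f <- m$f[, c(1, 3, 2)]
  m
}

# axis-aligned box mesh
box_mesh <- function(dx = 30, dy = 20, dz = 10, center = c(0, 0, 0)) {
  s <- rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
             c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))
  v <- sweep(s %*% diag(c(dx, dy, dz) / 2), 2, center, "+")
  f <- rbind(c(1, 3, 2), c(1, 4, 3), c(5, 6, 7), c(5, 7, 8),
             c(1, 2, 6), c(1, 6, 5), c(2, 3, 7), c(2, 7, 6),
             c(3, 4, 8), c(3, 8, 7), c(4, 1, 5), c(4, 5, 8))
  tri_mesh(v, f)
}

# full two-view registration fixture (renders, view poses, contours)
reg_fixture <- function(seed = 0, fragment = "F1") {
  memo(paste0("regfix_", seed, fragment), {
    carm <- carm_default()
    sc <- test_scene(seed)
    fr <- sc$fragments[[fragment]]
    fr$mesh <- mesh_precompute(fr$mesh)
    renders <- lapply(c(90, 60), function(a) test_render(seed, fragment, a))
    ipose <- lapply(renders, function(r)
      estimate_image_pose(detect_features(r$image, carm, sc$fid), sc$fid, carm))
    contours <- lapply(1:2, function(k)
      segment_contour(renders[[k]]$image,
        extract_silhouette(fr$mesh, carm, ipose[[k]]$pose, fr$pose_world)))
    list(sc = sc, fr = fr, renders = renders, ipose = ipose,
         contours = contours)
  })
}

# contour with seeded normal-direction jitter (for noise-sensitivity tests)
jitter_contour <- function(ct, sigma, seed) {
  pts <- ct$points
  n <- nrow(pts)
  nx <- c(2:n, 1); pv <- c(n, 1:(n - 1))
  tg <- pts[nx, ] - pts[pv, ]
  nrm <- cbind(tg[, 2], -tg[, 1]) / sqrt(rowSums(tg^2))
  set.seed(seed)
  contour2d(pts + nrm * rnorm(n, 0, sigma))
}

rt_random_seeded <- function(seed, max_angle_deg = 90, max_trans = 50) {
  set.seed(seed)
  rt_random(max_angle_deg, max_trans)
}

expect_pose_close <- function(a, b, tol_mm, tol_deg) {
  d <- rt_distance(a, b)
  expect_lt(d[["trans"]], tol_mm)
  expect_lt(d[["rot"]], tol_deg)
}
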