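#' Noise profile for synthetic fluoroscopic acquisition
#'
#' Bundles every stochastic degradation applied to synthetic data. The two
#' shipped profiles emulate the package's laboratory ("phantom-like") and
#' surgical ("cadaver-like") acquisition conditions; `noise_profile()` with
#' defaults is the clean/noiseless setting used by fixed-point tests.
#'
#' @param pixel_noise Additive Gaussian image noise, fraction of full scale.
#' @param feature_jitter_px Std. dev. added to detected feature positions.
#' @param contour_sigma_px Std. dev. of the perturbation applied to
#'   segmented contour samples.
#' @param occlusion_frac Fraction of contour samples occluded (contiguous
#'   arc) on `occlusion_view`.
#' @param occlusion_view View tag the occlusion applies to (default "LAT").
#' @param blur_sigma_px Extra image blur on top of the detector PSF.
#' @param psf_sigma_px Detector point-spread blur, always applied.
#' @param distortion Logical: render with the C-arm's synthesis distortion.
#' @export
noise_profile <- function(pixel_noise = 0, feature_jitter_px = 0,
                          contour_sigma_px = 0, occlusion_frac = 0,
                          occlusion_view = "LAT", blur_sigma_px = 0,
                          psf_sigma_px = 0.7, distortion = FALSE) {
  structure(list(pixel_noise = pixel_noise,
                 feature_jitter_px = feature_jitter_px,
                 contour_sigma_px = contour_sigma_px,
                 occlusion_frac = occlusion_frac,
                 occlusion_view = occlusion_view,
                 blur_sigma_px = blur_sigma_px,
                 psf_sigma_px = psf_sigma_px,
                 distortion = distortion),
            class = "noise_profile")
}

#' Shipped noise profiles
#'
#' @param name "clean", "phantom-like" or "cadaver-like".
#' @export
load_noise_profile <- function(name) {
  path <- system.file("extdata", paste0(gsub("-", "_", name), ".json"),
                      package = "fluororeg")
  if (!nzchar(path)) stop("unknown noise profile: ", name)
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(noise_profile, o)
}

# scanline fill of polygon loops with the nonzero-winding rule
fill_loops <- function(loops, nr, nc) {
  mask <- matrix(0, nr, nc)
  if (!length(loops)) return(mask)
  ax <- unlist(lapply(loops, function(p) p[, 1]))
  ay <- unlist(lapply(loops, function(p) p[, 2]))
  bx <- unlist(lapply(loops, function(p) p[c(2:nrow(p), 1), 1]))
  by <- unlist(lapply(loops, function(p) p[c(2:nrow(p), 1), 2]))
  v0 <- max(1L, floor(min(ay, by))); v1 <- min(nr, ceiling(max(ay, by)))
  for (v in v0:v1) {
    cr <- (ay <= v & by > v) | (ay > v & by <= v)
    if (!any(cr)) next
    xi <- ax[cr] + (v - ay[cr]) / (by[cr] - ay[cr]) * (bx[cr] - ax[cr])
    dir <- ifelse(by[cr] > ay[cr], 1L, -1L)
    o <- order(xi)
    xi <- xi[o]; dir <- dir[o]
    wind <- cumsum(dir)
    inside <- which(wind != 0)
    for (k in inside) {
      x_from <- max(1L, ceiling(xi[k]))
      x_to <- min(nc, floor(xi[k + 1]))
      if (x_from <= x_to) mask[v, x_from:x_to] <- 1
    }
  }
  mask
}

# anti-aliased winding fill: binary fill plus a signed-distance soft edge
# (1 px coverage ramp) for pixels near the polygon boundary; sub-pixel edge
# position is what contour segmentation localises, so the hard fill alone
# would quantise the silhouette to the pixel grid
fill_loops_aa <- function(loops, nr, nc, soft = 1) {
  mask <- fill_loops(loops, nr, nc)
  # candidate band: pixels within ~2 px of any polygon vertex/edge sample
  band_v <- integer(0); band_u <- integer(0)
  P <- do.call(rbind, lapply(loops, function(p) {
    n <- nrow(p); j <- c(seq_len(n)[-1], 1L)
    el <- sqrt(rowSums((p[j, , drop = FALSE] - p)^2))
    k <- pmax(ceiling(el / 0.5), 1L)
    do.call(rbind, lapply(seq_len(n), function(i) {
      tt <- seq(0, 1, length.out = k[i] + 1L)[-(k[i] + 1L)]
      cbind(p[i, 1] + tt * (p[j[i], 1] - p[i, 1]),
            p[i, 2] + tt * (p[j[i], 2] - p[i, 2]))
    }))
  }))
  iu <- round(P[, 1]); iv <- round(P[, 2])
  off <- expand.grid(du = -1:1, dv = -1:1)
  cand <- unique(data.frame(
    u = rep(iu, nrow(off)) + rep(off$du, each = length(iu)),
    v = rep(iv, nrow(off)) + rep(off$dv, each = length(iv))))
  cand <- cand[cand$u >= 1 & cand$u <= nc & cand$v >= 1 & cand$v <= nr, ]
  if (nrow(cand)) {
    # exact distance from band pixels to the polygon, signed by the mask
    d <- rep(Inf, nrow(cand))
    for (poly in loops) {
      n <- nrow(poly); j <- c(seq_len(n)[-1], 1L)
      A <- poly[j, , drop = FALSE] - poly
      al2 <- pmax(rowSums(A^2), 1e-30)
      m <- nrow(cand)
      tx <- (outer(cand$u, poly[, 1], "-") * rep(A[, 1], each = m) +
             outer(cand$v, poly[, 2], "-") * rep(A[, 2], each = m)) /
        rep(al2, each = m)
      tx[tx < 0] <- 0; tx[tx > 1] <- 1
      fx <- rep(poly[, 1], each = m) + tx * rep(A[, 1], each = m)
      fy <- rep(poly[, 2], each = m) + tx * rep(A[, 2], each = m)
      d2 <- (fx - cand$u)^2 + (fy - cand$v)^2
      d <- pmin(d, sqrt(d2[cbind(seq_len(m), max.col(-d2, ties.method = "first"))]))
    }
    inside <- mask[cbind(cand$v, cand$u)] > 0.5
    sd <- ifelse(inside, d, -d)
    mask[cbind(cand$v, cand$u)] <- pmin(pmax(sd / soft + 0.5, 0), 1)
  }
  mask
}

# soft disk and capsule primitives, drawn additively into `img`
draw_disk <- function(img, center, radius, intensity, soft = 1) {
  nr <- nrow(img); nc <- ncol(img)
  u0 <- max(1L, floor(center[1] - radius - 3))
  u1 <- min(nc, ceiling(center[1] + radius + 3))
  v0 <- max(1L, floor(center[2] - radius - 3))
  v1 <- min(nr, ceiling(center[2] + radius + 3))
  if (u0 > u1 || v0 > v1) return(img)
  us <- u0:u1; vs <- v0:v1
  du <- matrix(us - center[1], length(vs), length(us), byrow = TRUE)
  dv <- matrix(vs - center[2], length(vs), length(us))
  r <- sqrt(du^2 + dv^2)
  cov <- pmin(pmax((radius - r) / soft + 0.5, 0), 1)
  img[vs, us] <- img[vs, us] + intensity * cov
  img
}

draw_capsule <- function(img, p1, p2, r1, r2, intensity, soft = 1) {
  nr <- nrow(img); nc <- ncol(img)
  rmax <- max(r1, r2)
  u0 <- max(1L, floor(min(p1[1], p2[1]) - rmax - 3))
  u1 <- min(nc, ceiling(max(p1[1], p2[1]) + rmax + 3))
  v0 <- max(1L, floor(min(p1[2], p2[2]) - rmax - 3))
  v1 <- min(nr, ceiling(max(p1[2], p2[2]) + rmax + 3))
  if (u0 > u1 || v0 > v1) return(img)
  us <- u0:u1; vs <- v0:v1
  U <- matrix(us, length(vs), length(us), byrow = TRUE)
  V <- matrix(vs, length(vs), length(us))
  a <- p2 - p1
  al2 <- max(sum(a^2), 1e-12)
  tt <- pmin(pmax(((U - p1[1]) * a[1] + (V - p1[2]) * a[2]) / al2, 0), 1)
  d <- sqrt((p1[1] + tt * a[1] - U)^2 + (p1[2] + tt * a[2] - V)^2)
  rr <- r1 + tt * (r2 - r1)
  cov <- pmin(pmax((rr - d) / soft + 0.5, 0), 1)
  img[vs, us] <- img[vs, us] + intensity * cov
  img
}

gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  EBImage::gblur(img, sigma = sigma)
}

# intensities of the synthetic radiograph; chosen so that pin/bead over bone
# stays below 1 (clipping would bias sub-pixel feature localisation)
.render_levels <- list(background = 0.05, bone = 0.35, pin = 0.5, bead = 0.55)

#' Render one fluoroscopic view of a fragment + pin + registration tool
#'
#' Silhouette-shaded synthetic radiograph: the bone fragment is drawn as its
#' filled projected silhouette, the pin as a tapered capsule whose apex is
#' the exact projected pin tip, and the three fiducial beads as soft disks.
#' Ground truth (camera pose, true feature pixels, true silhouette) is
#' recorded before any degradation. Optional radial distortion, blur and
#' pixel noise are then applied per the noise profile.
#'
#' @param scene A `fragment_scene` from [generate_phantom()].
#' @param fragment "FEM", "F1" or "F2".
#' @param carm A [carm_model()]; its `distortion` is used when the profile
#'   asks for it.
#' @param view_angle_deg Orbit angle (AP = 90, LAT = 60).
#' @param noise A [noise_profile()].
#' @param seed Integer seed for the pixel noise.
#' @param standoff Source-to-scene-centre distance (mm); NULL = auto-fit.
#' @param pin_radius_mm,bead_radius_mm Rendered hardware radii.
#' @return List: `image` (matrix in [0,1]), `truth` (camera_pose, features
#'   4x2 px, silhouette [contour2d()], standoff).
#' @export
render_view <- function(scene, fragment, carm, view_angle_deg, noise = noise_profile(),
                        seed = 0, standoff = NULL, pin_radius_mm = 2.5,
                        bead_radius_mm = 3) {
  fr <- scene$fragments[[fragment]]
  if (is.null(fr)) stop("unknown fragment: ", fragment)
  fid <- scene$fid
  mesh_w <- mesh_transform(fr$mesh, fr$pose_world)
  feat_w <- fiducial_points(fid)      # world frame == RT frame
  pin_top_w <- c(0, 0, 30)
  ctr <- (apply(rbind(mesh_w$v, feat_w, pin_top_w), 2, min) +
          apply(rbind(mesh_w$v, feat_w, pin_top_w), 2, max)) / 2
  if (is.null(standoff))
    standoff <- fit_standoff(carm, rbind(mesh_w$v, feat_w, pin_top_w), ctr,
                             view_angle_deg)
  cam <- orbit_camera_pose(ctr, standoff, view_angle_deg)

  # ground truth before degradation
  feats_px <- project_points(carm, cam, feat_w,
                             distort = isTRUE(noise$distortion))
  sil <- extract_silhouette(fr$mesh, carm, cam, fr$pose_world)
  in_fov <- function(p) {
    r <- sqrt((p[, 1] - carm$principal_point[1])^2 +
              (p[, 2] - carm$principal_point[2])^2)
    all(r < carm$detector_diameter / carm$pixel_size / 2)
  }
  if (!in_fov(feats_px))
    stop("render error: fiducial outside the field of view")

  nr <- carm$image_shape[1]; nc <- carm$image_shape[2]
  lv <- .render_levels
  img <- matrix(lv$background, nr, nc)

  # bone silhouette loops (all of them, winding fill, anti-aliased edge)
  cam_inv <- rt_invert(cam)
  loops <- silhouette_loops(mesh_w, cam_inv$t)
  polys <- lapply(loops, function(l)
    project_points(carm, cam, mesh_w$v[l, , drop = FALSE], distort = FALSE))
  img <- img + lv$bone * fill_loops_aa(polys, nr, nc)

  # pin capsule: apex drawn exactly at the projected tip
  zs <- rt_apply(cam, rbind(fid$pin_tip, pin_top_w))[, 3]
  r_px <- pin_radius_mm * (carm$sid / zs) / carm$pixel_size
  tip2 <- project_points(carm, cam, fid$pin_tip, distort = FALSE)
  top2 <- project_points(carm, cam, pin_top_w, distort = FALSE)
  dir2 <- (top2 - tip2) / max(sqrt(sum((top2 - tip2)^2)), 1e-9)
  p1 <- tip2 + r_px[1] * dir2
  img <- draw_capsule(img, as.numeric(p1), as.numeric(top2), r_px[1], r_px[2],
                      lv$pin)

  # beads
  zb <- rt_apply(cam, fid$beads)[, 3]
  rb_px <- bead_radius_mm * (carm$sid / zb) / carm$pixel_size
  bead2 <- project_points(carm, cam, fid$beads, distort = FALSE)
  for (i in 1:3) img <- draw_disk(img, bead2[i, ], rb_px[i], lv$bead)

  img <- pmin(img, 1)
  if (isTRUE(noise$distortion) && !is.null(carm$distortion))
    img <- warp_distort(img, carm$distortion)
  img <- gaussian_blur(img, noise$psf_sigma_px + noise$blur_sigma_px)
  if (noise$pixel_noise > 0) {
    img <- with_seed(seed, img + matrix(stats::rnorm(nr * nc, 0, noise$pixel_noise),
                                        nr, nc))
  }
  img <- pmin(pmax(img, 0), 1)
  list(image = img,
       truth = list(camera_pose = cam, features = feats_px,
                    silhouette = sil, standoff = standoff,
                    view_angle_deg = view_angle_deg))
}

# choose the smallest standoff (coarse grid) that keeps the whole scene
# inside 90% of the detector radius in this view
fit_standoff <- function(carm, pts_w, ctr, view_angle_deg,
                         candidates = seq(600, 945, by = 15)) {
  rad_lim <- 0.95 * carm$detector_diameter / carm$pixel_size / 2
  for (s in candidates) {
    cam <- orbit_camera_pose(ctr, s, view_angle_deg)
    pc <- rt_apply(cam, pts_w)
    if (any(pc[, 3] <= 50) || any(pc[, 3] >= carm$sid - 20)) next
    px <- project_points(carm, cam, pts_w, distort = FALSE)
    r <- sqrt((px[, 1] - carm$principal_point[1])^2 +
              (px[, 2] - carm$principal_point[2])^2)
    if (max(r) < rad_lim) return(s)
  }
  stop("render error: scene does not fit the field of view at any standoff")
}

# apply radial distortion to a rendered image (inverse-mapped bilinear warp)
warp_distort <- function(img, dist) {
  nr <- nrow(img); nc <- ncol(img)
  rmax <- sqrt(nr^2 + nc^2)
  r_und <- seq(0, rmax, length.out = 512)
  r_dst <- apply_distortion(dist, cbind(dist$center[1] + r_und, dist$center[2]))[, 1] -
    dist$center[1]
  if (any(diff(r_dst) <= 0))
    stop("distortion not invertible on the detector")
  inv <- stats::splinefun(r_dst, r_und, method = "monoH.FC")
  U <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - dist$center[1]
  V <- matrix(seq_len(nr), nr, nc) - dist$center[2]
  R <- sqrt(U^2 + V^2)
  scale <- ifelse(R > 1e-9, inv(R) / R, 1)
  su <- dist$center[1] + U * scale
  sv <- dist$center[2] + V * scale
  matrix(bilinear_sample(img, as.vector(su), as.vector(sv)), nr, nc)
}

#' Render a calibration-grid image
#'
#' The ball-bearing grid phantom lies on the detector (unit magnification):
#' beads are drawn at exact lattice positions centred on the principal
#' point, with the C-arm's synthesis distortion applied to the bead centres
#' when configured, plus detector PSF and optional pixel noise.
#'
#' @param carm A [carm_model()] (with `distortion` set if wanted).
#' @param grid A [bead_grid_model()].
#' @param seed Pixel-noise seed.
#' @param pixel_noise Gaussian noise fraction (default 0).
#' @param psf_sigma_px Detector blur (default 0.7).
#' @return List: `image`, `truth` (ideal and rendered bead centres, px).
#' @export
render_calibration_image <- function(carm, grid, seed = 0, pixel_noise = 0,
                                     psf_sigma_px = 0.7) {
  lat <- grid_lattice_px(grid, carm)
  centers <- lat
  if (!is.null(carm$distortion))
    centers <- apply_distortion(carm$distortion, lat)
  nr <- carm$image_shape[1]; nc <- carm$image_shape[2]
  rad <- (grid$bead_diameter / 2) / carm$pixel_size
  lim <- carm$detector_diameter / carm$pixel_size / 2 - rad
  rr <- sqrt((centers[, 1] - carm$principal_point[1])^2 +
             (centers[, 2] - carm$principal_point[2])^2)
  if (any(rr > lim)) stop("grid does not fit the detector")
  img <- matrix(.render_levels$background, nr, nc)
  for (i in seq_len(nrow(centers)))
    img <- draw_disk(img, centers[i, ], rad, 0.85)
  img <- pmin(img, 1)
  img <- gaussian_blur(img, psf_sigma_px)
  if (pixel_noise > 0)
    img <- with_seed(seed, img + matrix(stats::rnorm(nr * nc, 0, pixel_noise),
                                        nr, nc))
  img <- pmin(pmax(img, 0), 1)
  list(image = img, truth = list(ideal = lat, rendered = centers))
}

# ideal lattice pixel positions of the grid at unit magnification
grid_lattice_px <- function(grid, carm) {
  pitch <- grid$spacing / carm$pixel_size
  us <- (seq_len(grid$n_cols) - (grid$n_cols + 1) / 2) * pitch +
    carm$principal_point[1]
  vs <- (seq_len(grid$n_rows) - (grid$n_rows + 1) / 2) * pitch +
    carm$principal_point[2]
  as.matrix(expand.grid(u = us, v = vs))
}
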