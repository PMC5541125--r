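#' C-arm imaging model
#'
#' Pinhole model of a C-arm fluoroscope: the X-ray source sits at the camera
#' origin, the optical axis is +z, and the image intensifier (detector) is
#' the plane z = `sid`. The source-to-image distance acts as the focal
#' length; image coordinates are in pixels with the principal point at the
#' detector centre and the image origin at the top-left pixel centre (1,1).
#'
#' @param sid Source-to-image distance (mm). Default 980, a typical mobile
#'   image-intensifier C-arm.
#' @param pixel_size Detector sampling pitch (mm/px). Default 0.224.
#' @param detector_diameter Circular field-of-view diameter (mm). Default 230.
#' @param image_shape Integer (rows, cols). Default covers the detector
#'   diameter at `pixel_size`.
#' @param principal_point Optional (u, v) px; defaults to the image centre.
#' @param distortion Optional [radial_distortion()] applied at synthesis time.
#' @return Object of class `carm_model`.
#' @export
carm_model <- function(sid = 980, pixel_size = 0.224, detector_diameter = 230,
                       image_shape = NULL, principal_point = NULL,
                       distortion = NULL) {
  stopifnot(sid > 0, pixel_size > 0, detector_diameter > 0)
  if (is.null(image_shape)) {
    n <- ceiling(detector_diameter / pixel_size)
    image_shape <- c(n, n)
  }
  image_shape <- as.integer(image_shape)
  if (detector_diameter / pixel_size > max(image_shape) + 1e-9)
    stop("image_shape too small to cover the detector diameter")
  if (is.null(principal_point))
    principal_point <- c((image_shape[2] + 1) / 2, (image_shape[1] + 1) / 2)
  structure(list(sid = sid, pixel_size = pixel_size,
                 detector_diameter = detector_diameter,
                 image_shape = image_shape,
                 principal_point = as.numeric(principal_point),
                 distortion = distortion),
            class = "carm_model")
}

#' @export
print.carm_model <- function(x, ...) {
  cat(sprintf("carm_model: SID %g mm, pixel %g mm/px, detector %g mm, image %d x %d px%s\n",
              x$sid, x$pixel_size, x$detector_diameter,
              x$image_shape[1], x$image_shape[2],
              if (is.null(x$distortion)) "" else ", with synthesis distortion"))
  invisible(x)
}

#' Radial distortion model (synthesis side)
#'
#' Even-power radial polynomial about a centre, modelling the pincushion
#' stretching of an image intensifier: a point at radius r px moves to
#' r' = r (1 + k1 r^2 + k2 r^4 + ...). Identity when all coefficients are 0.
#' This model is only used to synthesise distorted images; correction is
#' learned non-parametrically by the calibration module.
#'
#' @param coefficients Numeric vector (k1, k2, ...), units 1/px^2, 1/px^4, ...
#' @param center (u, v) px distortion centre.
#' @export
radial_distortion <- function(coefficients, center) {
  structure(list(coefficients = as.numeric(coefficients),
                 center = as.numeric(center)),
            class = "radial_distortion")
}

#' Default synthesis distortion for an image-intensifier C-arm
#'
#' A mild pincushion (k1 = 5e-8 px^-2, k2 = 1e-15 px^-4): a few pixels of
#' radial stretching at the detector periphery, the magnitude typical of a
#' calibrated image intensifier. Invertible across the whole detector.
#'
#' @param carm A [carm_model()] supplying the distortion centre.
#' @export
default_distortion <- function(carm = carm_model()) {
  radial_distortion(c(5e-8, 1e-15), carm$principal_point)
}

#' Apply radial distortion to pixel coordinates
#'
#' @param d A [radial_distortion()].
#' @param points_px n x 2 matrix (u, v) px.
#' @return n x 2 matrix of distorted coordinates.
#' @export
apply_distortion <- function(d, points_px) {
  stopifnot(inherits(d, "radial_distortion"))
  p <- as_points2(points_px)
  du <- p[, 1] - d$center[1]
  dv <- p[, 2] - d$center[2]
  r2 <- du^2 + dv^2
  scale <- rep(1, nrow(p))
  r2i <- rep(1, nrow(p))
  for (k in d$coefficients) {
    r2i <- r2i * r2
    scale <- scale + k * r2i
  }
  cbind(d$center[1] + du * scale, d$center[2] + dv * scale)
}

#' Project 3-D points through the C-arm model
#'
#' Points are mapped into the camera frame by `camera_pose` (world-to-camera)
#' and projected: `u = (x * sid / z) / pixel_size + pp_u`, analogously `v`.
#' If the model carries a synthesis-side distortion it is applied afterwards.
#'
#' @param carm A [carm_model()].
#' @param camera_pose `rigid_transform` mapping world to camera coordinates.
#' @param points3d n x 3 matrix (or length-3 vector) of world points, mm.
#' @param distort Apply `carm$distortion` if present (default TRUE).
#' @return n x 2 matrix of pixel coordinates.
#' @export
project_points <- function(carm, camera_pose, points3d, distort = TRUE) {
  stopifnot(inherits(carm, "carm_model"))
  x <- if (is.null(dim(points3d))) matrix(points3d, 1) else as.matrix(points3d)
  pc <- rt_apply(camera_pose, x)
  if (any(pc[, 3] <= 0))
    stop("invalid projection: point at or behind the X-ray source (z <= 0)")
  u <- (pc[, 1] * carm$sid / pc[, 3]) / carm$pixel_size + carm$principal_point[1]
  v <- (pc[, 2] * carm$sid / pc[, 3]) / carm$pixel_size + carm$principal_point[2]
  p <- cbind(u, v)
  if (distort && !is.null(carm$distortion))
    p <- apply_distortion(carm$distortion, p)
  unname(p)
}

#' Back-project pixels to unit bearing vectors in the camera frame
#'
#' @param carm A [carm_model()].
#' @param points_px n x 2 matrix of (undistorted) pixel coordinates.
#' @return n x 3 matrix of unit vectors from the source through each pixel.
#' @export
pixel_bearings <- function(carm, points_px) {
  p <- as_points2(points_px)
  x <- (p[, 1] - carm$principal_point[1]) * carm$pixel_size
  y <- (p[, 2] - carm$principal_point[2]) * carm$pixel_size
  v <- cbind(x, y, carm$sid)
  v / sqrt(rowSums(v^2))
}

#' Orbit camera pose for a C-arm view angle
#'
#' The C-arm orbits about the world z axis (in the package's synthetic scenes,
#' the pin/fiducial axis): the viewing direction at angle `theta` degrees is
#' (cos theta, sin theta, 0), so the anterior-posterior (90 deg) and lateral
#' (60 deg) views differ by a 30 degree rotation about the orbit axis. The
#' source is placed `standoff` mm from `center` against the viewing direction.
#'
#' @param center Length-3 world point the beam is aimed at (mm).
#' @param standoff Source-to-`center` distance (mm); must be < SID.
#' @param angle_deg Orbit angle in degrees (AP = 90, LAT = 60).
#' @return `rigid_transform` mapping world to camera coordinates.
#' @export
orbit_camera_pose <- function(center, standoff, angle_deg) {
  th <- angle_deg * pi / 180
  z <- c(cos(th), sin(th), 0)           # viewing direction
  y <- c(0, 0, 1)                       # image v axis ~ world z (pin axis)
  x <- c(y[2] * z[3] - y[3] * z[2],
         y[3] * z[1] - y[1] * z[3],
         y[1] * z[2] - y[2] * z[1])     # y cross z, right-handed
  R <- rbind(x, y, z)
  src <- center - standoff * z
  rigid_transform(R, as.numeric(-R %*% src))
}

as_points2 <- function(p) {
  if (is.null(dim(p))) matrix(as.numeric(p), ncol = 2) else {
    p <- as.matrix(p)
    stopifnot(ncol(p) == 2)
    p
  }
}
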