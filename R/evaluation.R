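#' Sample points area-uniformly on the labelled fracture surfaces
#'
#' Draws n points on the faces labelled as fracture surface, with
#' probability proportional to face area and uniform barycentric placement
#' within each face. Deterministic given the seed.
#'
#' @param mesh [tri_mesh()] with at least one fracture-labelled face.
#' @param n Number of points.
#' @param seed Integer seed.
#' @return An object of class `fracture_samples`: `points` (n x 3, model
#'   frame), `n`, `seed`.
#' @export
sample_fracture_surface <- function(mesh, n, seed = 0) {
  if (!any(mesh$fracture))
    stop("labelling error: mesh has no fracture-surface faces")
  fidx <- which(mesh$fracture)
  if (n == 0)
    return(structure(list(points = matrix(0, 0, 3), n = 0L, seed = seed),
                     class = "fracture_samples"))
  areas <- mesh_face_areas(mesh)[fidx]
  pts <- with_seed(seed, {
    pick <- sample(fidx, n, replace = TRUE, prob = areas)
    r1 <- sqrt(stats::runif(n)); r2 <- stats::runif(n)
    w <- cbind(1 - r1, r1 * (1 - r2), r1 * r2)
    a <- mesh$v[mesh$f[pick, 1], , drop = FALSE]
    b <- mesh$v[mesh$f[pick, 2], , drop = FALSE]
    c3 <- mesh$v[mesh$f[pick, 3], , drop = FALSE]
    a * w[, 1] + b * w[, 2] + c3 * w[, 3]
  })
  structure(list(points = pts, n = as.integer(n), seed = seed),
            class = "fracture_samples")
}

#' Surface target registration error (sTRE)
#'
#' Distance between matching fracture-surface points under the ground-truth
#' pose and the estimated pose: per point i,
#' `d_i = | pose_true(x_i) - pose_est(x_i) |` (mm). Reported as mean +/- sd
#' across points, the convention used for registration-accuracy tables.
#'
#' @param samples A `fracture_samples` (model frame).
#' @param pose_true,pose_est Model-to-world `rigid_transform`s.
#' @return An `stre_report`: `mean`, `sd`, `n`, `per_point` (mm).
#' @export
compute_stre <- function(samples, pose_true, pose_est) {
  if (samples$n == 0) stop("empty fracture sample set")
  a <- rt_apply(pose_true, samples$points)
  b <- rt_apply(pose_est, samples$points)
  d <- sqrt(rowSums((a - b)^2))
  structure(list(mean = mean(d), sd = stats::sd(d), n = samples$n,
                 per_point = d), class = "stre_report")
}

#' @export
print.stre_report <- function(x, ...) {
  cat(sprintf("sTRE: %.3f +/- %.3f mm (n = %d)\n", x$mean, x$sd, x$n))
  invisible(x)
}

#' Desired pose container
#'
#' A labelled rigid transform, used for the pre-operatively planned reduced
#' configuration of each fragment and for the derived robot target poses.
#'
#' @param pose A `rigid_transform`.
#' @param frame Character frame label.
#' @export
desired_pose <- function(pose, frame = "") {
  stopifnot(inherits(pose, "rigid_transform"))
  structure(list(pose = pose, frame = frame), class = "desired_pose")
}

#' Robot target pose from the registration chain
#'
#' Maps a planned fragment pose into the robot (fracture-manipulator) task
#' space: `RFM_P_d = RFM_T_P x IMG_T_F x F_P_d`, composing the tracked
#' robot-to-pin transform, the image-space-to-fragment registration and the
#' planned pose, in that exact order.
#'
#' @param rfm_to_pin `rigid_transform` from the optical tracker.
#' @param img_to_fragment `rigid_transform` from the registration framework.
#' @param desired A [desired_pose()] (planned fragment pose).
#' @return A [desired_pose()] in the robot task space.
#' @export
rfm_target_pose <- function(rfm_to_pin, img_to_fragment, desired) {
  stopifnot(inherits(desired, "desired_pose"))
  desired_pose(rt_compose(rfm_to_pin, rt_compose(img_to_fragment, desired$pose)),
               frame = "RFM")
}

#' Translational and rotational RMSE between achieved and desired poses
#'
#' Translational error is the RMSE of probe-point displacements between each
#' achieved and desired pose; rotational error is the RMSE of the geodesic
#' rotation angle between them.
#'
#' @param achieved_poses,desired_poses Lists of `rigid_transform` (equal
#'   length).
#' @param probe_points m x 3 matrix of probe points (mm).
#' @return Named vector `c(trans_mm, rot_deg)`.
#' @export
reduction_rmse <- function(achieved_poses, desired_poses, probe_points) {
  if (length(achieved_poses) != length(desired_poses))
    stop("achieved and desired pose lists differ in length")
  P <- as.matrix(probe_points)
  dt2 <- dr2 <- numeric(length(achieved_poses))
  for (i in seq_along(achieved_poses)) {
    a <- achieved_poses[[i]]; d <- desired_poses[[i]]
    dt2[i] <- mean(rowSums((rt_apply(a, P) - rt_apply(d, P))^2))
    dr2[i] <- rotation_angle_deg(a$R, d$R)^2
  }
  c(trans_mm = sqrt(mean(dt2)), rot_deg = sqrt(mean(dr2)))
}
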