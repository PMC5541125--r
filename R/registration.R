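#' Registration cost of a fragment pose against segmented contours
#'
#' Sum over views of the mean squared closest-point distance (px^2) between
#' the projected occluding contour of the mesh at `pose` and the segmented
#' contour spline of that view.
#'
#' @param mesh [tri_mesh()] in its model frame.
#' @param contours List of [contour2d()], one per view.
#' @param image_poses List of world-to-camera `rigid_transform`s (or
#'   `image_pose` objects), one per view.
#' @param carm [carm_model()].
#' @param pose Candidate model-to-world pose.
#' @param n_samples Silhouette samples per view (default 200).
#' @return Scalar cost (px^2), attribute `per_view` = RMS px per view.
#' @export
registration_cost <- function(mesh, contours, image_poses, carm, pose,
                              n_samples = 200) {
  per <- numeric(length(contours))
  total <- 0
  for (k in seq_along(contours)) {
    cam <- as_camera_pose(image_poses[[k]])
    s <- silhouette_samples(mesh, carm, cam, pose, n = n_samples)
    d <- contour_distance(contours[[k]], s$image)
    supp <- attr(d, "support")
    if (!any(supp)) stop("no silhouette sample faces a supported contour span")
    total <- total + mean(d[supp]^2)
    per[k] <- sqrt(mean(d[supp]^2))
  }
  structure(total, per_view = per)
}

as_camera_pose <- function(x) {
  if (inherits(x, "image_pose")) x$pose else x
}

#' Coarse alignment by seeded randomised search
#'
#' Programmatic stand-in for the surgeon's manual coarse alignment: samples
#' random pose perturbations (rotations anchored at the mesh centroid) in a
#' box around a starting guess and keeps the lowest registration cost. The
#' sample budget is spent in shrinking rounds - each round re-centres on
#' the best pose so far and contracts the box - because a single round of
#' uniform 6-DOF sampling essentially never lands close to the optimum.
#' Deterministic given the seed.
#'
#' @param mesh,contours,image_poses,carm As in [registration_cost()].
#' @param init Centre of the search box; NULL derives a centroid-based guess
#'   (two-view triangulation of the contour centroids, identity rotation).
#' @param search List: `n` total samples (200), `trans_mm` (15), `rot_deg`
#'   (15), `n_samples` silhouette samples per evaluation (80), `rounds` (3),
#'   `shrink` (0.35) box contraction per round, `polish` (4) damped
#'   Gauss-Newton iterations applied to the best sample (0 disables).
#' @param seed Integer seed.
#' @return Best `rigid_transform` found; attribute `cost` carries its score.
#' @export
coarse_align <- function(mesh, contours, image_poses, carm, init = NULL,
                         search = list(), seed = 0) {
  sp <- utils::modifyList(list(n = 200, trans_mm = 15, rot_deg = 15,
                               n_samples = 80, rounds = 4, shrink = 0.5,
                               polish = 4), search)
  if (is.null(init)) {
    ctr_w <- triangulate_contour_centroids(contours, image_poses, carm)
    init <- rigid_transform(diag(3), ctr_w - colMeans(mesh$v))
  }
  score <- function(p) tryCatch(
    as.numeric(registration_cost(mesh, contours, image_poses, carm, p,
                                 n_samples = sp$n_samples)),
    error = function(e) Inf)
  best <- init
  best_cost <- score(init)
  if (sp$n > 0 && (sp$trans_mm > 0 || sp$rot_deg > 0)) {
    per_round <- diff(round(seq(0, sp$n, length.out = sp$rounds + 1L)))
    with_seed(seed, {
      tr <- sp$trans_mm; rot <- sp$rot_deg
      for (round in seq_len(sp$rounds)) {
        center <- rt_apply(best, colMeans(mesh$v))
        base <- best
        # pattern probes (half-box along each DOF) walk the narrow cost
        # valleys that uniform 6-DOF sampling almost never tracks
        for (j in 1:6) for (sgn in c(-1, 1)) {
          d <- rep(0, 6)
          d[j] <- sgn * (if (j <= 3) rot * pi / 360 else tr / 2)
          p <- rt_update_about(base, d, center)
          cst <- score(p)
          if (cst < best_cost) { best <- p; best_cost <- cst }
        }
        for (i in seq_len(per_round[round])) {
          d <- c(stats::runif(3, -1, 1) * rot * pi / 180,
                 stats::runif(3, -1, 1) * tr)
          p <- rt_update_about(base, d, center)
          cst <- score(p)
          if (cst < best_cost) { best <- p; best_cost <- cst }
        }
        tr <- tr * sp$shrink
        rot <- rot * sp$shrink
      }
    })
  }
  searched <- sp$n > 0 && (sp$trans_mm > 0 || sp$rot_deg > 0)
  if (sp$polish > 0 && searched) {
    polished <- tryCatch(
      register_fragment(mesh, contours, image_poses, carm, best,
                        opts = list(n_samples = sp$n_samples,
                                    max_iter = sp$polish)),
      error = function(e) NULL)
    if (!is.null(polished) && polished$final_cost < best_cost) {
      best <- polished$fragment_pose
      best_cost <- polished$final_cost
    }
  }
  attr(best, "cost") <- best_cost
  best
}

# world point minimising distance to the source->centroid rays of each view
triangulate_contour_centroids <- function(contours, image_poses, carm) {
  A <- matrix(0, 3, 3); b <- c(0, 0, 0)
  for (k in seq_along(contours)) {
    cam <- as_camera_pose(image_poses[[k]])
    cam_inv <- rt_invert(cam)
    ctr_px <- colMeans(contours[[k]]$dense)
    d_cam <- pixel_bearings(carm, matrix(ctr_px, 1))
    d_w <- as.numeric(cam_inv$R %*% as.numeric(d_cam))
    o_w <- cam_inv$t
    P <- diag(3) - outer(d_w, d_w)
    A <- A + P
    b <- b + P %*% o_w
  }
  as.numeric(solve(A, b))
}

#' Register a fragment mesh to two posed fluoroscopic views
#'
#' Minimises the contour registration cost by alternating occluding-contour
#' resampling (correspondence update) with damped Gauss-Newton steps on the
#' 6-DOF pose. Converges when the relative cost change falls below `tol` or
#' after `max_iter` iterations; five consecutive rejected (cost-increasing)
#' steps raise a non-convergence error carrying the cost trace.
#'
#' @param mesh [tri_mesh()] (model frame).
#' @param contours List of segmented [contour2d()] per view.
#' @param image_poses List of view poses (world -> camera).
#' @param carm [carm_model()].
#' @param init Initial model-to-world pose (from [coarse_align()] or user).
#' @param opts List: `n_samples` (200), `max_iter` (200), `tol` (1e-8),
#'   `lambda0` (1e-3).
#' @param pin_pose Pose of the pin/RT frame in the world frame (identity in
#'   the package's synthetic scenes, where the world *is* the RT frame);
#'   used to derive the pin-to-fragment transform.
#' @return A `registration_result`: `fragment_pose`, `final_cost` (px^2),
#'   `iterations`, `converged`, `per_view_rms` (px), `pin_to_fragment`,
#'   `trace` (cost per accepted iteration).
#' @export
register_fragment <- function(mesh, contours, image_poses, carm, init,
                              opts = list(), pin_pose = rt_identity()) {
  op <- utils::modifyList(list(n_samples = 200, max_iter = 200, tol = 1e-8,
                               lambda0 = 1e-3), opts)
  cams <- lapply(image_poses, as_camera_pose)
  pose <- init
  init_full_cost <- as.numeric(registration_cost(mesh, contours, image_poses,
                                                 carm, init,
                                                 n_samples = op$n_samples))
  lambda <- op$lambda0
  trace <- c()
  prev_cost <- Inf
  consec_fail <- 0L
  iter <- 0L
  per_view <- rep(NA_real_, length(contours))
  ctr_model <- colMeans(mesh$v)
  repeat {
    iter <- iter + 1L
    ctr_w <- rt_apply(pose, ctr_model)
    # correspondence update: fixed silhouette sample set at current pose
    samp <- lapply(cams, function(cam)
      silhouette_samples(mesh, carm, cam, pose, n = op$n_samples))
    # robust trimming: samples far off the contour (occlusions, stray
    # edges) get zero weight for this iteration
    keepw <- lapply(seq_along(cams), function(k) {
      X <- samp[[k]]$model
      px <- project_points(carm, cams[[k]], rt_apply(pose, X), distort = FALSE)
      d <- contour_distance(contours[[k]], px)
      supp <- attr(d, "support")
      supp & d <= 3 * stats::median(d[supp]) + 1
    })
    resid <- function(d) {
      p2 <- rt_update_about(pose, d, ctr_w)
      unlist(lapply(seq_along(cams), function(k) {
        X <- samp[[k]]$model
        px <- project_points(carm, cams[[k]], rt_apply(p2, X), distort = FALSE)
        cd <- contour_distance(contours[[k]], px, closest = TRUE)
        as.vector((px - cd$closest) * keepw[[k]] / sqrt(max(sum(keepw[[k]]), 1)))
      }))
    }
    r0 <- resid(rep(0, 6))
    cost0 <- sum(r0^2)
    # numerical Jacobian (forward differences)
    J <- matrix(0, length(r0), 6)
    h <- c(rep(1e-5, 3), rep(1e-3, 3))
    for (j in 1:6) {
      d <- rep(0, 6); d[j] <- h[j]
      J[, j] <- (resid(d) - r0) / h[j]
    }
    JtJ <- crossprod(J)
    g <- crossprod(J, r0)
    accepted <- FALSE
    stalled <- FALSE
    for (try in 1:8) {
      step <- tryCatch(-solve(JtJ + lambda * diag(diag(JtJ) + 1e-12)),
                       error = function(e) NULL)
      if (is.null(step)) { lambda <- lambda * 10; next }
      d <- as.numeric(step %*% g)
      r1 <- resid(d)
      cost1 <- sum(r1^2)
      if (cost1 < cost0) {
        pose <- rt_update_about(pose, d, ctr_w)
        lambda <- max(lambda / 3, 1e-8)
        accepted <- TRUE
        trace <- c(trace, cost1)
        break
      }
      # already at a (local) minimum: a fully damped step changes nothing
      if (cost1 - cost0 <= op$tol * max(cost0, 1e-12) ||
          sqrt(sum(d^2)) < 1e-10) { stalled <- TRUE; break }
      lambda <- lambda * 8
    }
    if (stalled) { trace <- c(trace, cost0); break }
    if (!accepted) {
      consec_fail <- consec_fail + 1L
      if (consec_fail >= 5L) {
        err <- simpleError("registration non-convergence: cost increased for 5 consecutive damped steps")
        err$trace <- trace
        stop(err)
      }
      if (iter >= op$max_iter) break
      next
    }
    consec_fail <- 0L
    cost_now <- trace[length(trace)]
    if (is.finite(prev_cost) &&
        abs(prev_cost - cost_now) <= op$tol * max(prev_cost, 1e-12)) break
    prev_cost <- cost_now
    if (iter >= op$max_iter) break
  }
  final <- registration_cost(mesh, contours, image_poses, carm, pose,
                             n_samples = op$n_samples)
  res <- structure(list(
    fragment_pose = pose,
    final_cost = as.numeric(final),
    iterations = iter,
    converged = as.numeric(final) <= init_full_cost + 1e-12,
    per_view_rms = attr(final, "per_view"),
    pin_to_fragment = pin_to_fragment(pose, pin_pose),
    trace = trace), class = "registration_result")
  res
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("registration_result: cost %.4g px^2 after %d iterations (%s); per-view RMS %s px\n",
              x$final_cost, x$iterations,
              if (x$converged) "converged" else "not converged",
              paste(sprintf("%.3f", x$per_view_rms), collapse = ", ")))
  invisible(x)
}

#' Pin-to-fragment transform
#'
#' The quantity the intra-operative registration exists to produce: with the
#' fragment pose and the pin pose expressed in a common world frame, the
#' fragment pose in the pin frame is `invert(pin_pose) o fragment_pose`.
#' It is treated as constant for the rest of the operation.
#'
#' @param fragment_pose Model-to-world `rigid_transform`.
#' @param pin_pose Pin/RT-to-world `rigid_transform`.
#' @export
pin_to_fragment <- function(fragment_pose, pin_pose) {
  rt_compose(rt_invert(pin_pose), fragment_pose)
}

#' Serialise a registration result to JSON
#' @param path Output path.
#' @param res A `registration_result`.
#' @export
write_registration <- function(path, res) {
  jsonlite::write_json(list(
    fragment_pose = lapply(seq_len(4), function(i) rt_matrix(res$fragment_pose)[i, ]),
    pin_to_fragment = lapply(seq_len(4), function(i) rt_matrix(res$pin_to_fragment)[i, ]),
    final_cost = res$final_cost,
    iterations = res$iterations,
    converged = res$converged,
    per_view_rms = res$per_view_rms), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
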