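#' End-to-end synthetic registration experiment
#'
#' Replays the full intra-operative pipeline on synthetic phantoms, one
#' complete acquisition per seed: generate a fractured-femur scene, render a
#' calibration-grid image and calibrate the C-arm, then for each fragment
#' render the AP (90 deg) and LAT (60 deg) views, detect the fiducial
#' features, estimate both view poses, coarse-align and register the
#' fragment mesh to the segmented contours, and score the result with the
#' surface target registration error against ground truth.
#'
#' @param profile A [noise_profile()] or profile name
#'   ("clean", "phantom-like", "cadaver-like").
#' @param seeds Integer vector of per-run seeds.
#' @param fracture_type "Y" or "T" (default "Y").
#' @param carm Ground-truth [carm_model()] (default [carm_default()]).
#' @param n_stre Fracture-surface points per sTRE evaluation (default 100).
#' @param fragments Which fragments to process (default all three).
#' @param opts Low-level overrides: `coarse_n` (50), `coarse_samples` (60),
#'   `reg_samples` (150), `max_iter` (60), `seg_n` (200).
#' @param verbose Print one line per run.
#' @return data.frame with one row per (seed, fragment): sTRE mean/sd,
#'   registration cost and convergence, view-pose reprojection RMS, the
#'   estimated pixel size, and an `error` column ("" when the stage chain
#'   completed).
#' @export
run_experiment <- function(profile, seeds = 0:19, fracture_type = "Y",
                           carm = carm_default(), n_stre = 100,
                           fragments = c("FEM", "F1", "F2"),
                           opts = list(), verbose = FALSE) {
  if (is.character(profile)) profile <- load_noise_profile(profile)
  op <- utils::modifyList(list(coarse_n = 36, coarse_samples = 60,
                               coarse_rounds = 3,
                               reg_samples = 150, max_iter = 60,
                               seg_n = 200), opts)
  grid <- bead_grid_model()
  rows <- list()
  for (seed in seeds) {
    res <- tryCatch(
      run_single(profile, seed, fracture_type, carm, grid, n_stre,
                 fragments, op),
      error = function(e) {
        lapply(fragments, function(fr)
          data.frame(seed = seed, fragment = fr, stre_mean = NA_real_,
                     stre_sd = NA_real_, final_cost = NA_real_,
                     converged = FALSE, iterations = NA_integer_,
                     pose_rms_ap = NA_real_, pose_rms_lat = NA_real_,
                     pixel_size = NA_real_, error = conditionMessage(e)))
      })
    if (verbose) {
      for (r in res) message(sprintf(
        "seed %d %s: sTRE %.3f mm %s", seed, r$fragment, r$stre_mean,
        if (nzchar(r$error)) paste0("[", r$error, "]") else ""))
    }
    rows <- c(rows, res)
  }
  do.call(rbind, rows)
}

run_single <- function(profile, seed, fracture_type, carm, grid, n_stre,
                       fragments, op) {
  scene <- generate_phantom(phantom_spec(fracture_type, seed = seed))

  # intra-operative C-arm calibration from one grid image
  carm_syn <- carm
  cal_img <- render_calibration_image(carm_syn, grid, seed = seed * 13 + 1,
                                      pixel_noise = profile$pixel_noise)
  cal <- calibrate_carm(cal_img$image, grid, carm)
  carm_est <- carm_model(sid = carm$sid, pixel_size = cal$pixel_size_estimate,
                         detector_diameter = carm$detector_diameter,
                         image_shape = carm$image_shape,
                         principal_point = carm$principal_point)

  views <- c(AP = 90, LAT = 60)
  out <- list()
  for (fr_name in fragments) {
    row <- tryCatch(
      register_one_fragment(scene, fr_name, carm, carm_est, cal, views,
                            profile, seed, n_stre, op),
      error = function(e)
        data.frame(seed = seed, fragment = fr_name, stre_mean = NA_real_,
                   stre_sd = NA_real_, final_cost = NA_real_,
                   converged = FALSE, iterations = NA_integer_,
                   pose_rms_ap = NA_real_, pose_rms_lat = NA_real_,
                   pixel_size = cal$pixel_size_estimate,
                   error = conditionMessage(e)))
    out[[fr_name]] <- row
  }
  out
}

register_one_fragment <- function(scene, fr_name, carm_true, carm_est, cal,
                                  views, profile, seed, n_stre, op) {
  fr <- scene$fragments[[fr_name]]
  fr$mesh <- mesh_precompute(fr$mesh)
  base_seed <- seed * 101 + match(fr_name, c("FEM", "F1", "F2"))

  renders <- lapply(seq_along(views), function(k)
    render_view(scene, fr_name, carm_true, views[k], noise = profile,
                seed = base_seed * 7 + k))

  # fiducial features -> view poses (with localisation jitter per profile)
  image_poses <- lapply(seq_along(views), function(k) {
    det <- detect_features(renders[[k]]$image, carm_est, scene$fid)
    if (profile$feature_jitter_px > 0) {
      det$points <- det$points + with_seed(base_seed * 11 + k,
        matrix(stats::rnorm(8, 0, profile$feature_jitter_px), 4, 2))
    }
    if (isTRUE(profile$distortion))
      det$points <- correct_points(cal$correction, det$points)
    estimate_image_pose(det, scene$fid, carm_est)
  })

  # surgeon-style manual initial alignment. Its defining property is what
  # the surgeon verifies on screen: the projected model contour roughly
  # overlays the image contour in both views (here within 12 px), while
  # depth (which the projections barely show) stays loose.
  manual <- with_seed(base_seed * 17 + 3, {
    depth_dir <- c(cos(75 * pi / 180), sin(75 * pi / 180), 0)
    lat_dir <- c(-depth_dir[2], depth_dir[1], 0)
    probes <- lapply(seq_along(views), function(k)
      silhouette_samples(fr$mesh, carm_est, image_poses[[k]]$pose,
                         fr$pose_world, n = 40))
    ctr_w <- rt_apply(fr$pose_world, colMeans(fr$mesh$v))
    scale <- 1
    cand <- fr$pose_world
    for (try in 1:25) {
      dt <- stats::runif(1, -2, 2) * scale * lat_dir +
        stats::runif(1, -2, 2) * scale * c(0, 0, 1) +
        stats::runif(1, -8, 8) * scale * depth_dir
      dr <- stats::runif(3, -1, 1) * 5 * scale * pi / 180
      cand <- rt_update_about(fr$pose_world, c(dr, dt), ctr_w)
      off <- max(vapply(seq_along(views), function(k) {
        X <- probes[[k]]$model
        p0 <- probes[[k]]$image
        p1 <- project_points(carm_est, image_poses[[k]]$pose,
                             rt_apply(cand, X), distort = FALSE)
        max(sqrt(rowSums((p1 - p0)^2)))
      }, 1))
      if (off <= 12) break
      scale <- scale * 0.85
    }
    cand
  })

  # contour segmentation from a given pose's projection, with the
  # profile's contour perturbation and occlusion applied
  segment_at <- function(init_pose) {
    lapply(seq_along(views), function(k) {
      init <- extract_silhouette(fr$mesh, carm_est, image_poses[[k]]$pose,
                                 init_pose)
      occl <- NULL
      is_occ_view <- names(views)[k] == profile$occlusion_view
      if (profile$occlusion_frac > 0 && is_occ_view) {
        n_occ <- floor(op$seg_n * profile$occlusion_frac)
        start <- with_seed(base_seed * 19 + k, sample.int(op$seg_n, 1))
        occl <- rep(FALSE, op$seg_n)
        occl[((start + seq_len(n_occ) - 2L) %% op$seg_n) + 1L] <- TRUE
      }
      ct <- segment_contour(renders[[k]]$image, init,
                            params = list(n_samples = op$seg_n,
                                          occluded_mask = occl))
      if (profile$contour_sigma_px > 0) {
        pts <- ct$points
        nrm <- contour_normals(pts)
        pts <- pts + nrm * with_seed(base_seed * 23 + k,
          stats::rnorm(nrow(pts), 0, profile$contour_sigma_px))
        # denoise the measured contour before registration (local
        # quadratic: no inward shrinkage of the condylar curves)
        pts <- smooth_contour_sg(pts, window = 9, breaks = attr(ct, "breaks"))
        ct <- contour2d(pts, closed = TRUE, breaks = attr(ct, "breaks"))
      }
      ct
    })
  }

  # pass 1: segment from the manual pose, coarse-align, register;
  # pass 2: re-segment at the registered pose (its projection matches the
  # imaged contour far better than the manual one) and register again
  contours <- segment_at(manual)
  coarse <- coarse_align(fr$mesh, contours, image_poses, carm_est,
                         init = manual,
                         search = list(n = op$coarse_n, trans_mm = 10,
                                       rot_deg = 8, rounds = op$coarse_rounds,
                                       n_samples = op$coarse_samples),
                         seed = base_seed * 29 + 7)
  # multi-start guard: the alternating correspondence/Gauss-Newton scheme
  # has init-dependent local minima; when the fit from the coarse init is
  # implausibly poor for this noise level, restart from the manual pose
  reg <- tryCatch(
    register_fragment(fr$mesh, contours, image_poses, carm_est, coarse,
                      opts = list(n_samples = op$reg_samples,
                                  max_iter = op$max_iter)),
    error = function(e) NULL)
  sigma_eff <- 0.45 * profile$contour_sigma_px
  cost_gate <- max(0.06, 2 * sigma_eff^2 + 0.05)
  if (is.null(reg) || reg$final_cost > cost_gate) {
    alt <- tryCatch(
      register_fragment(fr$mesh, contours, image_poses, carm_est, manual,
                        opts = list(n_samples = op$reg_samples,
                                    max_iter = op$max_iter)),
      error = function(e) NULL)
    if (!is.null(alt) && (is.null(reg) || alt$final_cost < reg$final_cost))
      reg <- alt
  }
  if (is.null(reg)) stop("registration failed from both inits")
  contours <- segment_at(reg$fragment_pose)
  reg <- register_fragment(fr$mesh, contours, image_poses, carm_est,
                           reg$fragment_pose,
                           opts = list(n_samples = op$reg_samples,
                                       max_iter = op$max_iter))

  samp <- sample_fracture_surface(fr$mesh, n_stre, seed = base_seed * 31 + 5)
  stre <- compute_stre(samp, fr$pose_world, reg$fragment_pose)
  data.frame(seed = seed, fragment = fr_name, stre_mean = stre$mean,
             stre_sd = stre$sd, final_cost = reg$final_cost,
             converged = reg$converged, iterations = reg$iterations,
             pose_rms_ap = image_poses[[1]]$rms_reprojection,
             pose_rms_lat = image_poses[[2]]$rms_reprojection,
             pixel_size = carm_est$pixel_size, error = "")
}

contour_normals <- function(pts) {
  n <- nrow(pts)
  nxt <- c(seq_len(n)[-1], 1L); prv <- c(n, seq_len(n)[-n])
  tang <- pts[nxt, , drop = FALSE] - pts[prv, , drop = FALSE]
  tl <- pmax(sqrt(rowSums(tang^2)), 1e-12)
  cbind(tang[, 2], -tang[, 1]) / tl
}

#' Summarise an experiment table in registration-accuracy-table form
#'
#' @param results data.frame from [run_experiment()].
#' @return data.frame with one row per fragment: mean and sd of the
#'   per-run sTRE means, run counts and failure counts.
#' @export
summarise_experiment <- function(results) {
  sp <- split(results, results$fragment)
  out <- do.call(rbind, lapply(sp, function(d) {
    ok <- is.finite(d$stre_mean)
    data.frame(fragment = d$fragment[1],
               stre_mean = mean(d$stre_mean[ok]),
               stre_sd = stats::sd(d$stre_mean[ok]),
               n_runs = nrow(d), n_failed = sum(!ok))
  }))
  rownames(out) <- NULL
  out[match(c("FEM", "F1", "F2"), out$fragment), , drop = FALSE]
}
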