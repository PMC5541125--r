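#' Registration-tool fiducial geometry
#'
#' The registration tool (RT) carries three radiopaque beads in a radiolucent
#' body and mounts on an orthopaedic pin so that the RT and pin coordinate
#' frames coincide. Together with the pin's sharp tip this gives four known
#' 3-D points for view-pose estimation. The four points must be non-coplanar
#' and have pairwise-distinct distances so their image labels are
#' unambiguous.
#'
#' @param bead_centers 3 x 3 matrix of bead centres (mm, RT frame).
#' @param pin_tip Length-3 pin-tip point (mm, RT frame).
#' @export
fiducial_geometry <- function(bead_centers, pin_tip) {
  beads <- as.matrix(bead_centers)
  stopifnot(all(dim(beads) == c(3L, 3L)), length(pin_tip) == 3L)
  pts <- rbind(beads, pin_tip)
  vol <- abs(det(cbind(pts[2, ] - pts[1, ], pts[3, ] - pts[1, ],
                       pts[4, ] - pts[1, ]))) / 6
  if (vol <= 50)
    stop("fiducial points too close to coplanar (tetrahedron volume <= 50 mm^3)")
  d <- as.vector(stats::dist(pts))
  if (min(abs(diff(sort(d)))) <= 2)
    stop("fiducial pairwise distances not distinct by > 2 mm; labelling ambiguous")
  structure(list(beads = unname(beads), pin_tip = as.numeric(pin_tip),
                 labels = c("bead1", "bead2", "bead3", "pin_tip")),
            class = "fiducial_geometry")
}

#' All four fiducial points as a matrix (beads then pin tip)
#' @param fid A [fiducial_geometry()].
#' @export
fiducial_points <- function(fid) rbind(fid$beads, fid$pin_tip)

#' Labelled 2-D feature detections for one view
#'
#' @param points 4 x 2 matrix of pixel coordinates.
#' @param labels Character labels, a permutation of bead1..3, pin_tip.
#' @param covariance_px2 Optional scalar localisation variance (px^2).
#' @export
feature_detections <- function(points,
                               labels = c("bead1", "bead2", "bead3", "pin_tip"),
                               covariance_px2 = NA_real_) {
  points <- as.matrix(points)
  stopifnot(nrow(points) == 4L, ncol(points) == 2L,
            setequal(labels, c("bead1", "bead2", "bead3", "pin_tip")),
            !anyDuplicated(labels))
  o <- match(c("bead1", "bead2", "bead3", "pin_tip"), labels)
  structure(list(points = unname(points[o, , drop = FALSE]),
                 labels = c("bead1", "bead2", "bead3", "pin_tip"),
                 covariance_px2 = covariance_px2),
            class = "feature_detections")
}

# ---- P3P ---------------------------------------------------------------

# Grunert-style P3P: all poses consistent with 3 world points and their
# bearing vectors. The quartic in v = s3/s1 is built by exact polynomial
# elimination of u = s2/s1. Returns a list of candidate camera poses
# (world -> camera rigid transforms).
p3p_solve <- function(world_pts, bearings) {
  P <- as.matrix(world_pts); J <- as.matrix(bearings)
  stopifnot(all(dim(P) == c(3L, 3L)), all(dim(J) == c(3L, 3L)))
  J <- J / sqrt(rowSums(J^2))
  a2 <- sum((P[2, ] - P[3, ])^2)
  b2 <- sum((P[1, ] - P[3, ])^2)
  c2 <- sum((P[1, ] - P[2, ])^2)
  ca <- sum(J[2, ] * J[3, ]); cb <- sum(J[1, ] * J[3, ]); cg <- sum(J[1, ] * J[2, ])

  # Q(v) = (c2/b2)(1 - 2 cb v + v^2); R(v) = (a2/b2)(1 - 2 cb v + v^2)
  base <- c(1, -2 * cb, 1)
  Qp <- (c2 / b2) * base
  Rp <- (a2 / b2) * base
  # u = N(v)/D(v), N = Q - R - 1 + v^2, D = 2(ca v - cg)
  Np <- Qp - Rp + c(-1, 0, 1)
  Dp <- c(-2 * cg, 2 * ca)
  # constraint: D^2 + N^2 - 2 cg N D - Q D^2 = 0  -> quartic in v
  pmul <- function(x, y) {       # polynomial product, ascending coefs
    out <- numeric(length(x) + length(y) - 1L)
    for (i in seq_along(x)) out[i:(i + length(y) - 1L)] <-
        out[i:(i + length(y) - 1L)] + x[i] * y
    out
  }
  padd <- function(...) {
    ps <- list(...)
    n <- max(vapply(ps, length, 1L))
    Reduce(`+`, lapply(ps, function(p) c(p, numeric(n - length(p)))))
  }
  quart <- padd(pmul(Dp, Dp), pmul(Np, Np), -2 * cg * pmul(Np, Dp),
                -pmul(Qp, pmul(Dp, Dp)))
  quart <- quart / max(abs(quart))
  roots <- polyroot(quart)             # polyroot takes ascending coefficients
  v <- Re(roots[abs(Im(roots)) < 1e-3 * (1 + abs(Re(roots)))])
  v <- v[v > 0]
  # polish real roots by Newton iteration (double roots lose accuracy)
  dquart <- quart[-1] * seq_len(length(quart) - 1L)
  pv <- function(p, x) sum(p * x^(seq_along(p) - 1L))
  v <- vapply(v, function(vi) {
    for (it in 1:20) {
      dfd <- pv(dquart, vi)
      if (abs(dfd) < 1e-14) break
      step <- pv(quart, vi) / dfd
      vi <- vi - step
      if (abs(step) < 1e-14) break
    }
    vi
  }, 1)
  v <- v[v > 0]
  v <- v[!duplicated(round(v, 9))]
  cands <- list()
  for (vi in v) {
    D <- 2 * (ca * vi - cg)
    if (abs(D) < 1e-12) next
    ui <- ((c2 - a2) / b2 * (1 - 2 * cb * vi + vi^2) - 1 + vi^2) / D
    rad <- 1 + vi^2 - 2 * vi * cb
    if (rad <= 0 || ui <= 0) next
    s1 <- sqrt(b2 / rad)
    Y <- rbind(s1 * J[1, ], ui * s1 * J[2, ], vi * s1 * J[3, ])
    cands[[length(cands) + 1L]] <- absolute_orientation(P, Y)
  }
  cands
}

# Least-squares rigid transform T with T(P_i) ~ Y_i (Kabsch / Horn).
absolute_orientation <- function(P, Y) {
  Pc <- colMeans(P); Yc <- colMeans(Y)
  H <- crossprod(sweep(P, 2, Pc), sweep(Y, 2, Yc))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigid_transform(R, Yc - as.numeric(R %*% Pc))
}

#' Estimate the 6-DOF pose of a fluoroscopic view from fiducial detections
#'
#' Perspective-4-point: the three beads give up to four P3P candidate poses;
#' the pin-tip reprojection disambiguates them (candidates whose predicted
#' tip lands farther than `tip_gate_px` from the detected tip are dropped);
#' the surviving candidates are refined by Levenberg-Marquardt least squares
#' over all four points and the global minimum returned.
#'
#' @param det [feature_detections()] with undistorted pixel coordinates.
#' @param fid [fiducial_geometry()].
#' @param carm [carm_model()] (calibrated; distortion is ignored here).
#' @param tip_gate_px Disambiguation gate on the pin-tip residual (default 20).
#' @return An `image_pose`: list with `pose` (RT frame -> camera frame),
#'   `rms_reprojection` (px) and `per_point_residuals` (px).
#' @export
estimate_image_pose <- function(det, fid, carm, tip_gate_px = 20) {
  stopifnot(inherits(det, "feature_detections"),
            inherits(fid, "fiducial_geometry"))
  X <- fiducial_points(fid)
  obs <- det$points
  bear <- pixel_bearings(carm, obs[1:3, , drop = FALSE])
  cands <- p3p_solve(fid$beads, bear)
  if (!length(cands))
    stop("degenerate fiducial configuration: P3P produced no feasible pose")
  keep <- list()
  viable <- list()
  for (cand in cands) {
    pc <- rt_apply(cand, fid$pin_tip)
    if (pc[3] <= 0) next
    viable[[length(viable) + 1L]] <- cand
    tip <- project_points(carm, cand, fid$pin_tip, distort = FALSE)
    if (sqrt(sum((tip - obs[4, ])^2)) <= tip_gate_px)
      keep[[length(keep) + 1L]] <- cand
  }
  # under heavy detection noise the exact 3-point solutions can all throw
  # the distant tip beyond the gate; the 4-point refinement, not the gate,
  # is then the arbiter
  if (!length(keep)) keep <- viable
  if (!length(keep))
    stop("degenerate configuration: no feasible P3P candidate (all place the pin tip behind the source)")
  best <- NULL
  for (cand in keep) {
    res_fn <- function(d) {
      pose <- rt_update(cand, d)
      pc <- rt_apply(pose, X)
      if (any(pc[, 3] <= 0)) return(rep(1e6, 8))
      as.vector(project_points(carm, pose, X, distort = FALSE) - obs)
    }
    fit <- minpack.lm::nls.lm(par = rep(0, 6), fn = res_fn,
                              control = minpack.lm::nls.lm.control(
                                maxiter = 100, ftol = 1e-15, ptol = 1e-12))
    pose <- rt_update(cand, fit$par)
    r <- matrix(res_fn(fit$par), ncol = 2)
    per <- sqrt(rowSums(r^2))
    rms <- sqrt(mean(per^2))
    if (is.null(best) || rms < best$rms_reprojection) {
      best <- structure(list(pose = pose, rms_reprojection = rms,
                             per_point_residuals = per,
                             converged = fit$info %in% 1:4),
                        class = "image_pose")
    }
  }
  if (best$rms_reprojection > tip_gate_px)
    stop(sprintf("degenerate configuration: best refined pose leaves %.1f px reprojection RMS (gate %g px)",
                 best$rms_reprojection, tip_gate_px))
  if (!isTRUE(best$converged))
    warning("pose refinement did not report clean convergence")
  best
}

# ---- automated feature detection ---------------------------------------

#' Detect and label the fiducial features in a fluoroscopic image
#'
#' Automated stand-in for manual feature identification: the radiopaque
#' beads and the metal pin saturate the image, so a fixed high threshold
#' followed by connected-component labelling separates them. The three most
#' circular small components become bead candidates, the large elongated one
#' the pin; the tip is localised to sub-pixel precision by the half-maximum
#' crossing of the intensity profile along the pin axis. Label assignment
#' (which bead is which, which pin end is the tip) is chosen as the
#' hypothesis with the lowest perspective-4-point reprojection RMS.
#'
#' @param image Numeric matrix in [0, 1] (rows = v, cols = u), undistorted.
#' @param carm [carm_model()].
#' @param fid [fiducial_geometry()] used for labelling.
#' @param params List of overrides: `threshold` (default 0.8), `min_area` px
#'   (default 30), `tip_gate_px` (default 20).
#' @return [feature_detections()] with labels resolved.
#' @export
detect_features <- function(image, carm, fid, params = list()) {
  p <- utils::modifyList(list(threshold = 0.47, min_area = 30,
                              tip_gate_px = 20), params)
  bw <- image > p$threshold
  if (!any(bw)) stop("feature detection error: no bright features found")
  lab <- EBImage::bwlabel(bw)
  n <- max(lab)
  comps <- vector("list", n)
  idx <- which(lab > 0, arr.ind = TRUE)
  labs <- lab[lab > 0]
  for (i in seq_len(n)) {
    pix <- idx[labs == i, , drop = FALSE]
    if (nrow(pix) < p$min_area) next
    uv <- cbind(pix[, 2], pix[, 1])       # (u, v)
    w <- image[pix] - p$threshold
    ctr <- colSums(uv * w) / sum(w)
    cc <- stats::cov.wt(uv, wt = w / sum(w))$cov
    ev <- eigen(cc, symmetric = TRUE)$values
    comps[[i]] <- list(uv = uv, centroid = ctr, area = nrow(pix),
                       elong = sqrt(max(ev) / max(min(ev), 1e-9)))
  }
  comps <- Filter(Negate(is.null), comps)
  if (length(comps) < 4)
    stop("feature detection error: fewer than 4 candidate features in view")
  elong <- vapply(comps, `[[`, 1, "elong")
  area <- vapply(comps, `[[`, 1, "area")
  pin_i <- which(elong > 3)
  if (!length(pin_i))
    stop("feature detection error: no elongated pin component found")
  pin_i <- pin_i[which.max(area[pin_i])]
  bead_i <- setdiff(order(elong), pin_i)
  bead_i <- bead_i[seq_len(min(3L, length(bead_i)))]
  if (length(bead_i) < 3)
    stop("feature detection error: fewer than 3 bead components found")
  beads_px <- t(vapply(comps[bead_i], `[[`, numeric(2), "centroid"))
  tips <- pin_tip_candidates(image, comps[[pin_i]], p$threshold)

  # resolve labelling: bead permutations x tip ends by P4P reprojection RMS
  perms <- matrix(c(1,2,3, 1,3,2, 2,1,3, 2,3,1, 3,1,2, 3,2,1),
                  ncol = 3, byrow = TRUE)
  best <- NULL
  for (ti in seq_along(tips)) {
    for (pi in seq_len(nrow(perms))) {
      pts <- rbind(beads_px[perms[pi, ], , drop = FALSE], tips[[ti]])
      det <- feature_detections(pts)
      ip <- tryCatch(
        estimate_image_pose(det, fid, carm, tip_gate_px = p$tip_gate_px),
        error = function(e) NULL)
      if (!is.null(ip) && (is.null(best) || ip$rms_reprojection < best$rms)) {
        best <- list(det = det, rms = ip$rms_reprojection)
      }
    }
  }
  if (is.null(best))
    stop("labelling error: no bead/tip assignment is geometrically consistent")
  best$det
}

# Sub-pixel pin-tip estimates for both ends of the pin component.
#
# The centreline near each end is localised by symmetric gradient-edge
# midpoints: per axial station, the lateral intensity profile's two extreme
# gradients mark the pin walls, and their midpoint is background-invariant
# (an intensity-weighted centroid would be biased where the pin crosses the
# bone silhouette). A line fit over stations is extrapolated to the tip,
# which is then found as the half-maximum crossing of the axial profile.
pin_tip_candidates <- function(image, comp, threshold) {
  uv <- comp$uv
  ctr <- comp$centroid
  cc <- stats::cov.wt(uv)$cov
  ax <- eigen(cc, symmetric = TRUE)$vectors[, 1]
  lat_ax <- c(-ax[2], ax[1])
  s <- as.vector((uv - matrix(ctr, nrow(uv), 2, byrow = TRUE)) %*% ax)
  half_w <- stats::quantile(abs((uv - matrix(ctr, nrow(uv), 2, byrow = TRUE)) %*% lat_ax),
                            0.95)
  lapply(c(-1, 1), function(sgn) {
    send <- if (sgn > 0) max(s) else min(s)
    span <- max(s) - min(s)
    stations <- send - sgn * seq(half_w + 3, min(0.45 * span, 90), by = 4)
    lat_off <- seq(-(half_w + 6), half_w + 6, by = 0.1)
    cen <- rep(NA_real_, length(stations))
    mid0 <- which.min(abs(lat_off))
    for (k in seq_along(stations)) {
      pu <- ctr[1] + stations[k] * ax[1] + lat_off * lat_ax[1]
      pv <- ctr[2] + stations[k] * ax[2] + lat_off * lat_ax[2]
      prof <- bilinear_sample(image, pu, pv)
      # half-maximum wall crossings, per side (background-level invariant)
      hi <- stats::median(prof[abs(lat_off) < max(half_w - 5, 2)])
      loL <- stats::median(prof[lat_off < -(half_w + 3)])
      loR <- stats::median(prof[lat_off > half_w + 3])
      cross <- function(side) {
        half <- (hi + if (side < 0) loL else loR) / 2
        ii <- if (side < 0) mid0:1 else mid0:length(prof)
        below <- which(prof[ii] < half)
        if (!length(below) || min(below) == 1) return(NA_real_)
        j <- min(below)
        a <- ii[j - 1]; b <- ii[j]
        fr <- (prof[a] - half) / (prof[a] - prof[b])
        lat_off[a] + fr * (lat_off[b] - lat_off[a])
      }
      eL <- cross(-1); eR <- cross(1)
      if (is.finite(eL) && is.finite(eR)) cen[k] <- (eL + eR) / 2
    }
    ok <- is.finite(cen)
    if (sum(ok) >= 3) {
      fit <- stats::lm.fit(cbind(1, stations[ok]), cen[ok])
      c0 <- fit$coefficients[1]; c1 <- fit$coefficients[2]
    } else { c0 <- 0; c1 <- 0 }
    cen_at <- function(t) c0 + c1 * t
    # axial half-maximum crossing along the fitted centreline
    ts <- seq(send - sgn * 8, send + sgn * 6, by = sgn * 0.05)
    pu <- ctr[1] + ts * ax[1] + cen_at(ts) * lat_ax[1]
    pv <- ctr[2] + ts * ax[2] + cen_at(ts) * lat_ax[2]
    prof <- bilinear_sample(image, pu, pv)
    hi <- stats::median(prof[seq_len(20)])
    lo <- min(prof)
    half <- (hi + lo) / 2
    below <- which(prof < half)
    fallback <- c(ctr[1] + send * ax[1] + cen_at(send) * lat_ax[1],
                  ctr[2] + send * ax[2] + cen_at(send) * lat_ax[2])
    if (!length(below) || min(below) == 1) return(fallback)
    k <- min(below)
    frac <- (prof[k - 1] - half) / (prof[k - 1] - prof[k])
    tcross <- ts[k - 1] + frac * (ts[k] - ts[k - 1])
    c(ctr[1] + tcross * ax[1] + cen_at(tcross) * lat_ax[1],
      ctr[2] + tcross * ax[2] + cen_at(tcross) * lat_ax[2])
  })
}

#' Bilinear image sampling
#'
#' @param image Matrix (rows = v, cols = u), pixel centres at integers.
#' @param u,v Numeric vectors of sample coordinates.
#' @return Sampled intensities; samples outside the image return 0.
#' @export
bilinear_sample <- function(image, u, v) {
  nr <- nrow(image); nc <- ncol(image)
  u0 <- floor(u); v0 <- floor(v)
  fu <- u - u0; fv <- v - v0
  get <- function(vv, uu) {
    ok <- uu >= 1 & uu <= nc & vv >= 1 & vv <= nr
    out <- numeric(length(uu))
    out[ok] <- image[cbind(vv[ok], uu[ok])]
    out
  }
  (1 - fu) * (1 - fv) * get(v0, u0) +
    fu * (1 - fv) * get(v0, u0 + 1) +
    (1 - fu) * fv * get(v0 + 1, u0) +
    fu * fv * get(v0 + 1, u0 + 1)
}
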