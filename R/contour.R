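#' Closed 2-D contour with spline resampling and closest-point queries
#'
#' Stores an ordered (closed) point list in pixel coordinates together with
#' a periodic cubic-spline resampling, parameterised by normalised arc
#' length, used for closest-point distance queries during registration.
#'
#' @param points n x 2 matrix of ordered pixel coordinates (n >= 8).
#' @param closed Logical; only closed contours are supported downstream.
#' @param smooth Integer half-width of a circular moving-average smoother
#'   applied before spline fitting (0 = interpolate the raw points). The
#'   smoothing is bounded so knots stay within 0.5 px of the input.
#' @param n_dense Number of dense resampled points backing distance queries.
#' @param breaks Optional logical per input point: TRUE marks the span from
#'   point i to point i+1 as unsupported (an occluded/dropped region that
#'   the spline merely bridges). Distance queries can report whether their
#'   closest point lies on a supported span.
#' @export
contour2d <- function(points, closed = TRUE, smooth = 0, n_dense = 600,
                      breaks = NULL) {
  p <- as.matrix(points)
  stopifnot(ncol(p) == 2)
  # drop consecutive duplicates
  keep <- c(TRUE, rowSums(abs(diff(p))) > 1e-9)
  p <- p[keep, , drop = FALSE]
  if (!is.null(breaks)) breaks <- breaks[keep]
  if (nrow(p) < 8) stop("contour needs at least 8 distinct points")
  if (smooth > 0) {
    ps <- p
    n <- nrow(p)
    w <- -smooth:smooth
    for (i in seq_len(n)) {
      idx <- ((i - 1 + w) %% n) + 1
      avg <- colMeans(p[idx, , drop = FALSE])
      # bound the smoothing displacement at 0.5 px
      d <- avg - p[i, ]
      dn <- sqrt(sum(d^2))
      if (dn > 0.5) d <- d * 0.5 / dn
      ps[i, ] <- p[i, ] + d
    }
    p <- ps
  }
  pc <- rbind(p, p[1, ])
  d <- sqrt(rowSums(diff(pc)^2))
  tt <- c(0, cumsum(d))
  len <- tt[length(tt)]
  tt <- tt / len
  ts <- seq(0, 1, length.out = n_dense + 1L)[-(n_dense + 1L)]
  dense <- cbind(
    stats::spline(tt, pc[, 1], method = "periodic", xout = ts)$y,
    stats::spline(tt, pc[, 2], method = "periodic", xout = ts)$y)
  support <- rep(TRUE, length(ts))
  if (!is.null(breaks) && any(breaks)) {
    span <- findInterval(ts, tt, rightmost.closed = TRUE)
    span[span < 1] <- 1; span[span > nrow(p)] <- nrow(p)
    support <- !breaks[span]
  }
  structure(list(points = unname(p), closed = closed, t = tt[-length(tt)],
                 dense = dense, support = support, length_px = len),
            class = "contour2d")
}

#' @export
print.contour2d <- function(x, ...) {
  cat(sprintf("contour2d: %d knots, length %.1f px, %s\n", nrow(x$points),
              x$length_px, if (x$closed) "closed" else "open"))
  invisible(x)
}

#' Evaluate the contour spline at normalised arc-length parameters
#' @param ct A [contour2d()].
#' @param ts Parameters in [0, 1).
#' @export
contour_eval <- function(ct, ts) {
  pc <- rbind(ct$points, ct$points[1, ])
  tt <- c(ct$t, 1)
  cbind(stats::spline(tt, pc[, 1], method = "periodic", xout = ts %% 1)$y,
        stats::spline(tt, pc[, 2], method = "periodic", xout = ts %% 1)$y)
}

#' Distance from points to a contour
#'
#' Exact point-to-segment distance against the dense spline resampling.
#'
#' @param ct A [contour2d()].
#' @param pts m x 2 matrix of query points (px).
#' @param closest Also return the closest points.
#' @return Vector of distances (px), or a list with `distance` and `closest`.
#' @export
contour_distance <- function(ct, pts, closest = FALSE) {
  D <- ct$dense
  nd <- nrow(D)
  X <- as_points2(pts)
  m <- nrow(X)
  # nearest dense vertex (one m x nd distance matrix), then the exact foot
  # point on its two adjacent segments - the dense sampling is fine enough
  # that the true closest segment is always adjacent to the nearest vertex
  d2v <- outer(X[, 1], D[, 1], "-")^2 + outer(X[, 2], D[, 2], "-")^2
  j <- max.col(-d2v, ties.method = "first")
  prev <- ((j - 2L) %% nd) + 1L
  best_d2 <- rep(Inf, m); bx <- numeric(m); by <- numeric(m)
  seg_id <- integer(m)
  for (s in 1:2) {
    a <- if (s == 1) prev else j
    b <- ((a %% nd) + 1L)
    ax <- D[a, 1]; ay <- D[a, 2]
    vx <- D[b, 1] - ax; vy <- D[b, 2] - ay
    vl2 <- pmax(vx^2 + vy^2, 1e-30)
    tt <- pmin(pmax(((X[, 1] - ax) * vx + (X[, 2] - ay) * vy) / vl2, 0), 1)
    fx <- ax + tt * vx; fy <- ay + tt * vy
    dd <- (fx - X[, 1])^2 + (fy - X[, 2])^2
    upd <- dd < best_d2
    best_d2[upd] <- dd[upd]; bx[upd] <- fx[upd]; by[upd] <- fy[upd]
    seg_id[upd] <- a[upd]
  }
  d <- sqrt(best_d2)
  supp <- if (is.null(ct$support)) rep(TRUE, m) else ct$support[seg_id]
  if (!closest) return(structure(d, support = supp))
  list(distance = d, closest = cbind(bx, by), support = supp)
}

# ---- occluding contours -------------------------------------------------

# silhouette edges of a mesh seen from a source point: mesh edges whose two
# adjacent faces face opposite ways; chained into ordered vertex loops
silhouette_loops <- function(mesh_world, source_w) {
  ef <- mesh_edge_faces(mesh_world)
  nrm <- mesh_face_normals(mesh_world, normalise = FALSE)
  ctr <- (mesh_world$v[mesh_world$f[, 1], , drop = FALSE] +
          mesh_world$v[mesh_world$f[, 2], , drop = FALSE] +
          mesh_world$v[mesh_world$f[, 3], , drop = FALSE]) / 3
  view <- ctr - matrix(source_w, nrow(ctr), 3, byrow = TRUE)
  front <- rowSums(nrm * view) < 0
  ok <- !is.na(ef$faces[, 2])
  f2 <- ef$faces[, 2]; f2[!ok] <- 1L
  sil <- ok & front[ef$faces[, 1]] != front[f2]
  edges <- ef$edges[sil, , drop = FALSE]
  if (!nrow(edges)) return(list())
  chain_edge_loops(edges)
}

# chain undirected edges into loops (generic vertices have degree 2)
chain_edge_loops <- function(edges) {
  ne <- nrow(edges)
  vmap <- split(rep(seq_len(ne), 2L), c(edges[, 1], edges[, 2]))
  used <- rep(FALSE, ne)
  loops <- list()
  for (e0 in seq_len(ne)) {
    if (used[e0]) next
    loop <- edges[e0, 1]
    cur_v <- edges[e0, 2]
    used[e0] <- TRUE
    repeat {
      loop <- c(loop, cur_v)
      cand <- vmap[[as.character(cur_v)]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      e <- cand[1]
      used[e] <- TRUE
      cur_v <- if (edges[e, 1] == cur_v) edges[e, 2] else edges[e, 1]
    }
    if (length(loop) >= 3 && loop[length(loop)] == loop[1])
      loop <- loop[-length(loop)]
    if (length(loop) >= 3) loops[[length(loops) + 1L]] <- loop
  }
  loops
}

polygon_area <- function(p) {
  n <- nrow(p)
  j <- c(seq_len(n)[-1], 1L)
  sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2]) / 2
}

#' Winding number of points with respect to a set of polygons
#'
#' @param loops List of k x 2 polygon matrices (closed implicitly).
#' @param pts m x 2 query points.
#' @return Integer vector of summed winding numbers.
#' @export
winding_number <- function(loops, pts) {
  X <- as_points2(pts)
  w <- integer(nrow(X))
  for (poly in loops) {
    n <- nrow(poly)
    j <- c(seq_len(n)[-1], 1L)
    ay <- poly[, 2]; by <- poly[j, 2]
    ax <- poly[, 1]; bx <- poly[j, 1]
    for (i in seq_len(nrow(X))) {
      py <- X[i, 2]; px <- X[i, 1]
      cr <- (ay <= py & by > py) | (ay > py & by <= py)
      if (!any(cr)) next
      xi <- ax[cr] + (py - ay[cr]) / (by[cr] - ay[cr]) * (bx[cr] - ax[cr])
      dir <- ifelse(by[cr] > ay[cr], 1L, -1L)
      w[i] <- w[i] + sum(dir[xi > px])
    }
  }
  w
}

#' Project the occluding contour of a posed mesh into a view
#'
#' Computes the silhouette of `mesh` under `pose` seen by the camera at
#' `camera_pose`, as an ordered closed pixel contour (the projection of the
#' mesh's occluding-contour edges; the largest loop is returned).
#'
#' @param mesh A [tri_mesh()] in its model frame.
#' @param carm A [carm_model()].
#' @param camera_pose World-to-camera `rigid_transform`.
#' @param pose Model-to-world `rigid_transform` of the mesh.
#' @return A [contour2d()] in pixel coordinates.
#' @export
extract_silhouette <- function(mesh, carm, camera_pose, pose) {
  mw <- mesh_transform(mesh, pose)
  cam_inv <- rt_invert(camera_pose)
  zc <- rt_apply(camera_pose, mw$v)[, 3]
  if (any(zc <= 0))
    stop("projection error: mesh at or behind the X-ray source")
  loops <- silhouette_loops(mw, cam_inv$t)
  if (!length(loops)) stop("no silhouette found (degenerate mesh?)")
  polys <- lapply(loops, function(l)
    project_points(carm, camera_pose, mw$v[l, , drop = FALSE], distort = FALSE))
  areas <- vapply(polys, function(p) abs(polygon_area(p)), 1)
  p <- densify_edges(polys[[which.max(areas)]], max_len = 5)
  contour2d(densify_polygon(p, 16L), closed = TRUE)
}

# split long polygon edges so that downstream spline interpolation cannot
# bulge away from the true (piecewise-straight) projected silhouette
densify_edges <- function(p, max_len = 5) {
  n <- nrow(p)
  j <- c(seq_len(n)[-1], 1L)
  el <- sqrt(rowSums((p[j, , drop = FALSE] - p)^2))
  k <- pmax(ceiling(el / max_len), 1L)
  if (all(k == 1L)) return(p)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    tt <- seq(0, 1, length.out = k[i] + 1L)[-(k[i] + 1L)]
    out[[i]] <- cbind(p[i, 1] + tt * (p[j[i], 1] - p[i, 1]),
                      p[i, 2] + tt * (p[j[i], 2] - p[i, 2]))
  }
  do.call(rbind, out)
}

# subdivide polygon edges until at least n_min vertices (coarse meshes can
# project to very few silhouette vertices, e.g. a face-on box)
densify_polygon <- function(p, n_min) {
  while (nrow(p) < n_min) {
    n <- nrow(p)
    j <- c(seq_len(n)[-1], 1L)
    mid <- (p + p[j, , drop = FALSE]) / 2
    out <- matrix(0, 2 * n, 2)
    out[seq(1, 2 * n, by = 2), ] <- p
    out[seq(2, 2 * n, by = 2), ] <- mid
    p <- out
  }
  p
}

# 3-D occluding-contour sample points of a posed mesh, filtered to the
# visible outline (a small outward step in the image leaves the projected
# union), subsampled to ~n points evenly along projected arc length.
silhouette_samples <- function(mesh, carm, camera_pose, pose, n = 200,
                               eps_px = 2) {
  mw <- mesh_transform(mesh, pose)
  cam_inv <- rt_invert(camera_pose)
  loops <- silhouette_loops(mw, cam_inv$t)
  if (!length(loops)) stop("no silhouette found")
  polys <- lapply(loops, function(l)
    project_points(carm, camera_pose, mw$v[l, , drop = FALSE], distort = FALSE))
  pts3 <- NULL; pts2 <- NULL; arc <- NULL
  for (k in seq_along(loops)) {
    p2 <- polys[[k]]
    X3 <- mw$v[loops[[k]], , drop = FALSE]
    # subdivide long projected edges (3-D and 2-D in tandem: interpolated
    # points stay on the mesh silhouette edges)
    nk0 <- nrow(p2)
    jn0 <- c(seq_len(nk0)[-1], 1L)
    el <- sqrt(rowSums((p2[jn0, , drop = FALSE] - p2)^2))
    ks <- pmax(ceiling(el / 5), 1L)
    if (any(ks > 1L)) {
      p2l <- vector("list", nk0); x3l <- vector("list", nk0)
      for (i in seq_len(nk0)) {
        tt <- seq(0, 1, length.out = ks[i] + 1L)[-(ks[i] + 1L)]
        p2l[[i]] <- cbind(p2[i, 1] + tt * (p2[jn0[i], 1] - p2[i, 1]),
                          p2[i, 2] + tt * (p2[jn0[i], 2] - p2[i, 2]))
        x3l[[i]] <- matrix(X3[i, ], length(tt), 3, byrow = TRUE) +
          outer(tt, X3[jn0[i], ] - X3[i, ])
      }
      p2 <- do.call(rbind, p2l)
      X3 <- do.call(rbind, x3l)
    }
    nk <- nrow(p2)
    jn <- c(seq_len(nk)[-1], 1L)
    tang <- p2[jn, , drop = FALSE] - p2
    tl <- pmax(sqrt(rowSums(tang^2)), 1e-12)
    nrm2 <- cbind(tang[, 2], -tang[, 1]) / tl
    ctr <- colMeans(p2)
    outward <- rowSums(nrm2 * sweep(p2, 2, ctr)) >= 0
    nrm2[!outward, ] <- -nrm2[!outward, , drop = FALSE]
    # pre-subsample before the (per-point) visibility test
    cand_i <- seq_len(nk)
    if (nk > 3L * n) cand_i <- unique(round(seq(1, nk, length.out = 3L * n)))
    test <- p2[cand_i, , drop = FALSE] + eps_px * nrm2[cand_i, , drop = FALSE]
    vis <- winding_number(polys, test) == 0
    if (!any(vis)) next
    keep_i <- cand_i[vis]
    pts3 <- rbind(pts3, X3[keep_i, , drop = FALSE])
    pts2 <- rbind(pts2, p2[keep_i, , drop = FALSE])
  }
  if (is.null(pts3) || nrow(pts3) < 6)
    stop("silhouette entirely occluded")
  if (nrow(pts3) > n) {
    sel <- unique(round(seq(1, nrow(pts3), length.out = n)))
    pts3 <- pts3[sel, , drop = FALSE]
    pts2 <- pts2[sel, , drop = FALSE]
  }
  # return model-frame points so pose updates re-project them
  pose_inv <- rt_invert(pose)
  list(model = rt_apply(pose_inv, pts3), image = pts2)
}

#' Smooth a closed contour with a circular Savitzky-Golay filter
#'
#' Local quadratic smoothing of the x/y coordinate sequences against arc
#' index. Unlike a moving average, the quadratic fit does not shrink curved
#' regions inward (its leading bias term is the fourth derivative), so it
#' denoises a measured bone contour without biasing the condylar curves.
#' Windows crossing an unsupported break are left unsmoothed.
#'
#' @param points n x 2 ordered closed contour points (px).
#' @param window Odd window length (default 9).
#' @param breaks Optional logical per point marking unsupported spans
#'   (span i runs from point i to i+1).
#' @return n x 2 smoothed points.
#' @export
smooth_contour_sg <- function(points, window = 9, breaks = NULL) {
  p <- as.matrix(points)
  n <- nrow(p)
  if (window %% 2 != 1) stop("window must be odd")
  k <- (window - 1L) %/% 2L
  if (n < window + 2L) return(p)
  i <- -k:k
  X <- cbind(1, i, i^2)
  w0 <- (solve(crossprod(X)) %*% t(X))[1, ]   # centre-point SG weights
  out <- p
  for (j in seq_len(n)) {
    idx <- ((j - 1 + i) %% n) + 1
    if (!is.null(breaks)) {
      spans <- ((j - 1 + (-k):(k - 1)) %% n) + 1
      if (any(breaks[spans])) next
    }
    out[j, ] <- c(sum(w0 * p[idx, 1]), sum(w0 * p[idx, 2]))
  }
  out
}

#' Refine a contour on an image by normal-direction gradient search
#'
#' Active-contour style one-shot refinement: each sample of the initial
#' contour is moved along its local normal to the strongest image-gradient
#' magnitude within a search window; samples with no gradient above
#' `grad_threshold` are treated as occluded and dropped; a smoothing spline
#' is refit through the survivors.
#'
#' @param image Numeric matrix in [0, 1].
#' @param init_contour A [contour2d()] from the coarse-aligned model
#'   projection.
#' @param params Overrides: `n_samples` (200), `window_px` (15),
#'   `step_px` (0.5), `grad_threshold` (0.04), `max_occluded_frac` (0.6),
#'   `occluded_mask` (optional logical per sample, forces drop).
#' @return A [contour2d()]; attribute `kept_frac` reports the surviving
#'   sample fraction.
#' @export
segment_contour <- function(image, init_contour, params = list()) {
  p <- utils::modifyList(list(n_samples = 200, window_px = 15, step_px = 0.25,
                              grad_threshold = 0.04, max_occluded_frac = 0.6,
                              consistency_px = 2.5, occluded_mask = NULL),
                         params)
  ts <- seq(0, 1, length.out = p$n_samples + 1L)[-(p$n_samples + 1L)]
  s <- contour_eval(init_contour, ts)
  s2 <- contour_eval(init_contour, ts + 1e-4)
  tang <- s2 - s
  tl <- pmax(sqrt(rowSums(tang^2)), 1e-12)
  nrm <- cbind(tang[, 2], -tang[, 1]) / tl
  # high-curvature samples (silhouette corners) have ambiguous normals and
  # biased edge crossings; treat them as unreliable
  tu <- tang / tl
  nn <- p$n_samples
  turn <- acos(pmin(pmax(rowSums(tu * tu[c(2:nn, 1), , drop = FALSE]), -1), 1))
  sharp <- pmax(turn, turn[c(nn, 1:(nn - 1))]) > 15 * pi / 180
  offs <- seq(-p$window_px, p$window_px, by = p$step_px)
  no <- length(offs)
  uu <- rep(s[, 1], each = no) + rep(nrm[, 1], each = no) * offs
  vv <- rep(s[, 2], each = no) + rep(nrm[, 2], each = no) * offs
  prof <- matrix(bilinear_sample(image, uu, vv), nrow = no)
  grad <- abs(prof[c(2:no, no), ] - prof[c(1, 1:(no - 1)), ]) / (2 * p$step_px)
  grad[1, ] <- 0; grad[no, ] <- 0
  # prefer the local gradient maximum nearest the initial position over the
  # globally strongest one (a neighbouring structure, e.g. the pin, can
  # carry a stronger edge than the bone contour being tracked)
  pk <- integer(p$n_samples)
  for (i in seq_len(p$n_samples)) {
    g <- grad[, i]
    loc <- which(g >= max(p$grad_threshold, 0.4 * max(g)) &
                 g >= c(-Inf, g[-no]) & g >= c(g[-1], -Inf))
    pk[i] <- if (length(loc)) loc[which.min(abs(offs[loc]))] else which.max(g)
  }
  gmax <- grad[cbind(pk, seq_len(p$n_samples))]
  occ <- gmax < p$grad_threshold | pk <= 2 | pk >= no - 1 | sharp
  if (!is.null(p$occluded_mask)) occ <- occ | p$occluded_mask
  if (mean(occ) > p$max_occluded_frac)
    stop(sprintf("segmentation failure: %.0f%% of contour samples occluded",
                 100 * mean(occ)))
  # sub-pixel edge localisation: half-maximum crossing of the intensity
  # profile around the chosen gradient peak (phase-invariant under the
  # bilinear sampling, unlike a parabolic fit of the gradient)
  d_off <- numeric(p$n_samples)
  hw <- max(2L, round(2.5 / p$step_px))    # half-width of the crossing scan
  fw <- max(4L, round(5 / p$step_px))      # plateau estimation band
  for (i in which(!occ)) {
    k <- pk[i]
    lo_band <- max(1L, k - fw - hw):max(1L, k - hw)
    hi_band <- min(no, k + hw):min(no, k + hw + fw)
    m1 <- stats::median(prof[lo_band, i])
    m2 <- stats::median(prof[hi_band, i])
    half <- (m1 + m2) / 2
    jj <- max(1L, k - hw):min(no - 1L, k + hw)
    pr <- prof[, i]
    crossing <- jj[(pr[jj] - half) * (pr[jj + 1L] - half) <= 0]
    if (length(crossing)) {
      j <- crossing[which.min(abs(crossing + 0.5 - k))]
      fr <- (pr[j] - half) / (pr[j] - pr[j + 1L])
      d_off[i] <- offs[j] + fr * p$step_px
    } else {
      y0 <- grad[k - 1, i]; y1 <- grad[k, i]; y2 <- grad[k + 1, i]
      den <- y0 - 2 * y1 + y2
      frac <- if (abs(den) > 1e-12) 0.5 * (y0 - y2) / den else 0
      d_off[i] <- offs[k] + frac * p$step_px
    }
  }
  # displacement-consistency filter: a sample whose edge displacement
  # disagrees with its neighbours by several px has locked onto a stray
  # structure; treat it as occluded
  ki0 <- which(!occ)
  if (is.finite(p$consistency_px) && length(ki0) > 10) {
    dk <- d_off[ki0]
    nk0 <- length(dk)
    med_nb <- vapply(seq_len(nk0), function(i) {
      idx <- ((i - 1 + (-2:2)) %% nk0) + 1
      stats::median(dk[idx])
    }, 1)
    occ[ki0[abs(dk - med_nb) > p$consistency_px]] <- TRUE
  }
  keep <- !occ
  ki <- which(keep)
  pts <- s[keep, , drop = FALSE] + nrm[keep, , drop = FALSE] * d_off[keep]
  # spans that bridge dropped samples are unsupported (occluded regions are
  # dropped, not interpolated)
  nk <- length(ki)
  brk <- (ki[c(2:nk, 1)] - ki) %% p$n_samples != 1
  out <- contour2d(pts, closed = TRUE, smooth = 0, breaks = brk)
  attr(out, "kept_frac") <- mean(keep)
  attr(out, "breaks") <- brk
  out
}
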