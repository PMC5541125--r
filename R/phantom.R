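#' Synthetic fracture phantom specification
#'
#' Describes a procedural three-part distal-femur fracture phantom (the
#' 33-C1 analogue): a shaft that flares into a two-lobed condylar mass,
#' split by one transverse cut (separating the femoral shaft FEM from the
#' distal block) and one sagittal (T) or oblique (Y) cut (splitting the
#' distal block into condylar fragments F1 and F2). Every cut face is
#' labelled as fracture surface. Vertices can optionally be quantised to a
#' CT voxel grid to emulate CT-derived segmentation.
#'
#' @param fracture_type "Y" (oblique distal cut) or "T" (sagittal cut).
#' @param shaft_length Total bone length (mm).
#' @param shaft_radius Shaft radius (mm).
#' @param condyle_radius Base radius of the condylar mass (mm).
#' @param lobe Relative lobe amplitude of the condylar cross-section.
#' @param cut_z Transverse-cut height from the proximal end (mm).
#' @param cut_obliquity Slope dx/dz of the distal cut (0 for T; Y default 0.35).
#' @param ellipticity Relative cos(2 phi) modulation of the shaft
#'   cross-section (femoral shafts are not circular; this also makes the
#'   rotation about the shaft axis observable in silhouettes).
#' @param ridge Relative amplitude of a posterior longitudinal ridge on the
#'   shaft (linea aspera analogue).
#' @param bow Anterior bow sagitta of the shaft axis (mm).
#' @param ct_voxel CT voxel size (mm), default c(0.58, 0.58, 0.75).
#' @param quantise Quantise vertices to `ct_voxel` (default FALSE).
#' @param n_phi,n_z Angular / axial mesh resolution.
#' @param seed Seed controlling the small anatomical jitter of cuts and pins.
#' @export
phantom_spec <- function(fracture_type = c("Y", "T"), shaft_length = 140,
                         shaft_radius = 13, condyle_radius = 20, lobe = 0.55,
                         cut_z = 100, cut_obliquity = NULL,
                         ellipticity = 0.08, ridge = 0.12, bow = 4,
                         ct_voxel = c(0.58, 0.58, 0.75), quantise = FALSE,
                         n_phi = 48, n_z = 60, seed = 0) {
  fracture_type <- match.arg(fracture_type)
  if (is.null(cut_obliquity))
    cut_obliquity <- if (fracture_type == "Y") 0.35 else 0
  structure(list(fracture_type = fracture_type, shaft_length = shaft_length,
                 shaft_radius = shaft_radius, condyle_radius = condyle_radius,
                 lobe = lobe, cut_z = cut_z, cut_obliquity = cut_obliquity,
                 ellipticity = ellipticity, ridge = ridge, bow = bow,
                 ct_voxel = as.numeric(ct_voxel), quantise = quantise,
                 n_phi = as.integer(n_phi), n_z = as.integer(n_z),
                 seed = seed),
            class = "phantom_spec")
}

smoothstep <- function(x) { x <- pmin(pmax(x, 0), 1); x * x * (3 - 2 * x) }

# cross-section radius rho(z, phi): shaft flaring into a two-lobed condylar
# mass (lobes along +/- x), with elliptical shaft section and a posterior
# longitudinal ridge so the shaft is not a surface of revolution
phantom_radius <- function(spec, z, phi) {
  zr <- smoothstep((z - (spec$shaft_length - 55)) / 45)
  r0 <- spec$shaft_radius + (spec$condyle_radius - spec$shaft_radius) * zr
  a <- spec$lobe * zr
  shaft_w <- 1 - zr
  r0 * (1 + a * cos(phi)^2 +
          shaft_w * (spec$ellipticity * cos(2 * (phi - 0.4)) +
                     spec$ridge * exp(-angdiff(phi, 1.8)^2 / 0.5)))
}

angdiff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

phantom_ring <- function(spec, z) {
  phi <- seq(0, 2 * pi, length.out = spec$n_phi + 1L)[-(spec$n_phi + 1L)]
  r <- phantom_radius(spec, z, phi)
  zf <- z / spec$shaft_length
  cy <- spec$bow * 4 * zf * (1 - zf)    # anterior bow of the shaft axis
  cbind(r * cos(phi), cy + r * sin(phi), z)
}

# --- structured mesh assembly -------------------------------------------

# zip two ordered polylines (same orientation) into a triangle strip;
# params t1/t2 in [0,1] steer the advance. Returns triangles as rows of
# local indices: negative = index into P2.
zip_strip <- function(n1, t1, n2, t2) {
  tri <- matrix(0L, n1 + n2 - 2L, 3L)
  i <- 1L; j <- 1L; k <- 0L
  while (i < n1 || j < n2) {
    adv1 <- if (i >= n1) FALSE else if (j >= n2) TRUE else t1[i + 1L] <= t2[j + 1L]
    k <- k + 1L
    if (adv1) { tri[k, ] <- c(i, i + 1L, -j); i <- i + 1L }
    else { tri[k, ] <- c(i, -(j + 1L), -j); j <- j + 1L }
  }
  tri[seq_len(k), , drop = FALSE]
}

# accumulate mesh pieces
new_builder <- function() new.env(parent = emptyenv())
builder_init <- function(b) { b$v <- list(); b$f <- list(); b$lab <- list(); b$nv <- 0L }
add_verts <- function(b, v) {
  b$v[[length(b$v) + 1L]] <- v
  idx <- b$nv + seq_len(nrow(v))
  b$nv <- b$nv + nrow(v)
  idx
}
add_faces <- function(b, f, fracture = FALSE) {
  b$f[[length(b$f) + 1L]] <- f
  b$lab[[length(b$lab) + 1L]] <- rep(fracture, nrow(f))
}
builder_mesh <- function(b) {
  v <- do.call(rbind, b$v)
  f <- do.call(rbind, b$f)
  lab <- unlist(b$lab)
  # merge duplicate vertices so shared ring/cap borders become shared edges
  key <- paste(round(v[, 1], 7), round(v[, 2], 7), round(v[, 3], 7))
  uid <- match(key, unique(key))
  vv <- v[!duplicated(uid), , drop = FALSE]
  ff <- matrix(uid[f], ncol = 3)
  keep <- ff[, 1] != ff[, 2] & ff[, 2] != ff[, 3] & ff[, 1] != ff[, 3]
  tri_mesh(vv, ff[keep, , drop = FALSE], lab[keep])
}

# side wall between two closed rings with equal vertex count
add_ring_wall <- function(b, ring_lo, ring_hi) {
  n <- nrow(ring_lo)
  il <- add_verts(b, ring_lo); ih <- add_verts(b, ring_hi)
  j <- seq_len(n); jn <- c(seq_len(n)[-1], 1L)
  add_faces(b, rbind(cbind(il[j], il[jn], ih[jn]),
                     cbind(il[j], ih[jn], ih[j])))
}

# fan cap over a closed polygon; `up` gives outward normal +z (TRUE) or -z
add_cap <- function(b, poly, up, fracture = FALSE) {
  n <- nrow(poly)
  ctr <- colMeans(poly)
  ic <- add_verts(b, matrix(ctr, 1))
  ip <- add_verts(b, poly)
  j <- seq_len(n); jn <- c(seq_len(n)[-1], 1L)
  f <- if (up) cbind(rep(ic, n), ip[j], ip[jn]) else cbind(rep(ic, n), ip[jn], ip[j])
  add_faces(b, f, fracture)
}

# clip a closed ring polygon to the half-plane x >= c (side = +1) or x <= c
# (side = -1); returns the open polyline from entry to exit crossing,
# ordered consistently with the ring, with normalised params.
clip_ring <- function(ring, c0, side) {
  x <- ring[, 1]
  g <- side * (x - c0)
  n <- nrow(ring)
  nxt <- c(seq_len(n)[-1], 1L)
  cross <- which((g >= 0) != (g[nxt] >= 0))
  if (length(cross) != 2L)
    stop("degenerate cut: cross-section not split into two parts")
  cr_pt <- function(i) {
    j <- nxt[i]
    tt <- g[i] / (g[i] - g[j])
    ring[i, ] + tt * (ring[j, ] - ring[i, ])
  }
  p1 <- cr_pt(cross[1]); p2 <- cr_pt(cross[2])
  walk <- function(from, to) {
    idx <- integer(0); i <- from
    repeat {
      idx <- c(idx, i)
      if (i == to) break
      i <- (i %% n) + 1L
    }
    idx
  }
  run1 <- (cross[1] %% n) + 1L
  if (g[run1] >= 0) {
    poly <- rbind(p1, ring[walk(run1, cross[2]), , drop = FALSE], p2)
  } else {
    run2 <- (cross[2] %% n) + 1L
    poly <- rbind(p2, ring[walk(run2, cross[1]), , drop = FALSE], p1)
  }
  d <- sqrt(rowSums(diff(poly)^2))
  tt <- c(0, cumsum(d)); tt <- tt / tt[length(tt)]
  list(poly = poly, t = tt)
}

add_zipped_wall <- function(b, lo, hi) {
  i1 <- add_verts(b, lo$poly); i2 <- add_verts(b, hi$poly)
  tri <- zip_strip(nrow(lo$poly), lo$t, nrow(hi$poly), hi$t)
  f <- matrix(0L, nrow(tri), 3L)
  for (c3 in 1:3) {
    loc <- tri[, c3]
    pos <- loc > 0L
    f[pos, c3] <- i1[loc[pos]]
    f[!pos, c3] <- i2[-loc[!pos]]
  }
  add_faces(b, f)
}

# planar fracture band between consecutive chords (A_i -> B_i straight lines
# in the cut plane), oriented so the normal points away from `side`.
add_cut_band <- function(b, chords, side) {
  k <- length(chords)
  for (i in seq_len(k - 1L)) {
    a1 <- chords[[i]][1, ]; b1 <- chords[[i]][2, ]
    a2 <- chords[[i + 1L]][1, ]; b2 <- chords[[i + 1L]][2, ]
    i1 <- add_verts(b, rbind(a1, b1, a2, b2))
    f <- rbind(c(i1[1], i1[3], i1[4]), c(i1[1], i1[4], i1[2]))
    add_faces(b, f, fracture = TRUE)
  }
}

# consistent orientation + outward volume for an assembled fragment
orient_mesh <- function(mesh) {
  ef <- mesh_edge_faces(mesh)
  m <- nrow(mesh$f)
  # adjacency via shared edges
  adj <- ef$faces[!is.na(ef$faces[, 2]), , drop = FALSE]
  nb <- split(c(adj[, 2], adj[, 1]), c(adj[, 1], adj[, 2]))
  flip <- rep(NA, m)
  dir_key <- function(f) paste(f[, 1], f[, 2], f[, 3])
  edges_of <- function(fi, flipped) {
    f <- mesh$f[fi, ]
    if (flipped) f <- f[c(1, 3, 2)]
    rbind(c(f[1], f[2]), c(f[2], f[3]), c(f[3], f[1]))
  }
  for (start in seq_len(m)) {
    if (!is.na(flip[start])) next
    flip[start] <- FALSE
    queue <- start
    while (length(queue)) {
      fi <- queue[[1]]; queue <- queue[-1]
      e_i <- edges_of(fi, flip[fi])
      for (fj in nb[[as.character(fi)]]) {
        if (!is.na(flip[fj])) next
        e_j <- edges_of(fj, FALSE)
        # shared edge must appear in opposite directions
        shared_same <- any(paste(e_i[, 1], e_i[, 2]) %in% paste(e_j[, 1], e_j[, 2]))
        flip[fj] <- shared_same
        queue <- c(queue, fj)
      }
    }
  }
  f <- mesh$f
  f[flip, ] <- f[flip, c(1, 3, 2)]
  out <- tri_mesh(mesh$v, f, mesh$fracture)
  if (mesh_volume(out) < 0) out$f <- out$f[, c(1, 3, 2)]
  out
}

#' Generate a synthetic fractured-femur scene
#'
#' Builds the three watertight fragment meshes (FEM shaft, condylar F1 and
#' F2) with labelled fracture surfaces, places an orthopaedic pin and
#' registration-tool fiducial on each fragment, and records the ground-truth
#' fragment pose in each pin/RT frame. The per-fragment world frame is the
#' RT frame of that fragment's pin (the frame every downstream pose is
#' estimated in).
#'
#' @param spec A [phantom_spec()].
#' @param fid [fiducial_geometry()] placed on each pin (default shipped one).
#' @return A `fragment_scene`: list with `spec`, `fid`, `full_volume` (mm^3
#'   of the uncut solid) and `fragments`, a named list (FEM, F1, F2) of
#'   `mesh` ([tri_mesh()], model frame), `pin_pose` (RT frame -> model
#'   frame) and `pose_world` (model frame -> RT/world frame, the ground
#'   truth both for view rendering and sTRE).
#' @export
generate_phantom <- function(spec, fid = fiducial_default()) {
  stopifnot(inherits(spec, "phantom_spec"))
  rng <- with_seed(spec$seed + 1000L, list(
    cut_dz = stats::runif(1, -4, 4),
    obl_d = stats::runif(1, -0.04, 0.04),
    pin_rot = stats::runif(3, -5, 5) * pi / 180,
    pin_az = stats::runif(3, -1, 1) * 0.2,
    anch_dz = stats::runif(3, -3, 3)))
  zc <- spec$cut_z + rng$cut_dz
  m_obl <- if (spec$fracture_type == "Y") spec$cut_obliquity + rng$obl_d else 0
  L <- spec$shaft_length

  for (attempt in 1:3) {
    zlo <- seq(0, zc, length.out = max(12L, round(spec$n_z * zc / L)))
    zhi <- seq(zc, L, length.out = max(12L, spec$n_z - length(zlo) + 2L))
    rings_lo <- lapply(zlo, phantom_ring, spec = spec)
    rings_hi <- lapply(zhi, phantom_ring, spec = spec)

    # FEM: full tube 0..zc
    b <- new_builder(); builder_init(b)
    for (i in seq_len(length(rings_lo) - 1L))
      add_ring_wall(b, rings_lo[[i]], rings_lo[[i + 1L]])
    add_cap(b, rings_lo[[1L]], up = FALSE, fracture = FALSE)
    add_cap(b, rings_lo[[length(rings_lo)]], up = TRUE, fracture = TRUE)
    fem <- orient_mesh(builder_mesh(b))

    # distal halves
    halves <- lapply(c(1, -1), function(side) {
      b <- new_builder(); builder_init(b)
      clips <- lapply(seq_along(zhi), function(i)
        clip_ring(rings_hi[[i]], m_obl * (zhi[i] - zc), side))
      for (i in seq_len(length(clips) - 1L))
        add_zipped_wall(b, clips[[i]], clips[[i + 1L]])
      chords <- lapply(clips, function(cl)
        rbind(cl$poly[1, ], cl$poly[nrow(cl$poly), ]))
      add_cut_band(b, chords, side)
      close_poly <- function(cl) cl$poly   # open polyline + chord closes it
      add_cap(b, close_poly(clips[[1L]]), up = FALSE, fracture = TRUE)
      add_cap(b, close_poly(clips[[length(clips)]]), up = TRUE, fracture = FALSE)
      orient_mesh(builder_mesh(b))
    })
    f1 <- halves[[1]]; f2 <- halves[[2]]
    vols <- c(mesh_volume(fem), mesh_volume(f1), mesh_volume(f2))
    if (all(vols >= 1000)) break
    message("degenerate cut (fragment < 1000 mm^3); adjusting cut planes")
    zc <- zc + 6; m_obl <- m_obl * 0.7
  }

  full <- local({
    b <- new_builder(); builder_init(b)
    rings <- c(rings_lo, rings_hi[-1L])
    for (i in seq_len(length(rings) - 1L))
      add_ring_wall(b, rings[[i]], rings[[i + 1L]])
    add_cap(b, rings[[1L]], up = FALSE)
    add_cap(b, rings[[length(rings)]], up = TRUE)
    orient_mesh(builder_mesh(b))
  })

  if (spec$quantise) {
    q <- function(mesh) {
      mesh$v <- sweep(round(sweep(mesh$v, 2, spec$ct_voxel, "/")), 2,
                      spec$ct_voxel, "*")
      mesh
    }
    fem <- q(fem); f1 <- q(f1); f2 <- q(f2)
  }

  # pin placements: anchor (tip) point inside the fragment, direction outward
  mk_pin <- function(anchor, dir, jit_rot, jit_az) {
    d <- dir / sqrt(sum(dir^2))
    # small seeded deviation of the insertion axis
    perp <- c(-d[2], d[1], 0); perp <- perp / max(sqrt(sum(perp^2)), 1e-9)
    d <- rot_from_vec(perp * jit_rot) %*% d
    d <- rot_from_vec(c(0, 0, jit_az)) %*% d
    d <- as.numeric(d / sqrt(sum(d^2)))
    h <- c(0, 0, 1)
    ycol <- c(h[2] * d[3] - h[3] * d[2], h[3] * d[1] - h[1] * d[3],
              h[1] * d[2] - h[2] * d[1])
    ycol <- ycol / sqrt(sum(ycol^2))
    xcol <- c(ycol[2] * d[3] - ycol[3] * d[2], ycol[3] * d[1] - ycol[1] * d[3],
              ycol[1] * d[2] - ycol[2] * d[1])
    R <- cbind(xcol, ycol, d)
    t <- anchor - as.numeric(R %*% fid$pin_tip)
    rigid_transform(R, t)
  }
  pins <- list(
    FEM = mk_pin(c(4, 0, zc - 35 + rng$anch_dz[1]), c(1, 0.25, 0),
                 rng$pin_rot[1], rng$pin_az[1]),
    F1 = mk_pin(c(12, 0, zc + 22 + rng$anch_dz[2]), c(0.9, 0.3, 0.15),
                rng$pin_rot[2], rng$pin_az[2]),
    F2 = mk_pin(c(-12, 0, zc + 22 + rng$anch_dz[3]), c(-0.9, 0.3, 0.15),
                rng$pin_rot[3], rng$pin_az[3]))

  frags <- list(FEM = fem, F1 = f1, F2 = f2)
  fragments <- lapply(names(frags), function(nm) {
    list(name = nm, mesh = frags[[nm]], pin_pose = pins[[nm]],
         pose_world = rt_invert(pins[[nm]]))
  })
  names(fragments) <- names(frags)
  structure(list(spec = spec, fid = fid, fragments = fragments,
                 full_volume = mesh_volume(full)),
            class = "fragment_scene")
}

#' @export
print.fragment_scene <- function(x, ...) {
  cat(sprintf("fragment_scene (%s-type): volumes %s mm^3\n",
              x$spec$fracture_type,
              paste(sprintf("%s=%.0f", names(x$fragments),
                            vapply(x$fragments, function(f) mesh_volume(f$mesh), 1)),
                    collapse = ", ")))
  invisible(x)
}

# run code with a temporary RNG state (deterministic, side-effect free)
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", .GlobalEnv)
  old <- if (had) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, .GlobalEnv)
    else if (exists(".Random.seed", .GlobalEnv))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  force(expr)
}
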