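#' Triangle mesh with optional fracture-surface labels
#'
#' Minimal indexed triangle-mesh container used for CT-derived bone-fragment
#' geometry. `fracture` flags the faces that belong to a fracture surface
#' (the surfaces on which sTRE sample points are drawn).
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param fracture Logical length-m vector (default all FALSE).
#' @export
tri_mesh <- function(vertices, faces, fracture = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3,
            min(faces) >= 1L, max(faces) <= nrow(vertices))
  if (is.null(fracture)) fracture <- rep(FALSE, nrow(faces))
  stopifnot(length(fracture) == nrow(faces))
  structure(list(v = vertices, f = faces, fracture = as.logical(fracture)),
            class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d vertices, %d faces (%d fracture-labelled)\n",
              nrow(x$v), nrow(x$f), sum(x$fracture)))
  invisible(x)
}

#' Signed volume of a closed mesh
#'
#' Sum of signed tetrahedra against the origin; positive for outward-oriented
#' watertight meshes.
#'
#' @param mesh A [tri_mesh()].
#' @return Volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  a <- mesh$v[mesh$f[, 1], , drop = FALSE]
  b <- mesh$v[mesh$f[, 2], , drop = FALSE]
  c <- mesh$v[mesh$f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
      a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
      a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

#' Per-face areas
#' @param mesh A [tri_mesh()].
#' @export
mesh_face_areas <- function(mesh) {
  a <- mesh$v[mesh$f[, 1], , drop = FALSE]
  e1 <- mesh$v[mesh$f[, 2], , drop = FALSE] - a
  e2 <- mesh$v[mesh$f[, 3], , drop = FALSE] - a
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

#' Check watertightness
#'
#' A mesh is watertight here when every edge is shared by exactly two faces
#' with opposite winding.
#'
#' @param mesh A [tri_mesh()].
#' @return TRUE/FALSE with attribute `boundary_edges` (count).
#' @export
mesh_is_watertight <- function(mesh) {
  e <- mesh_directed_edges(mesh)
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  ok <- all(cnt == 2L)
  if (ok) {
    # opposite winding: directed edges must come in (a,b)/(b,a) pairs
    dkey <- paste(e[, 1], e[, 2])
    ok <- !anyDuplicated(dkey) && all(paste(e[, 2], e[, 1]) %in% dkey)
  }
  structure(ok, boundary_edges = sum(cnt != 2L))
}

mesh_directed_edges <- function(mesh) {
  f <- mesh$f
  rbind(cbind(f[, 1], f[, 2]), cbind(f[, 2], f[, 3]), cbind(f[, 3], f[, 1]))
}

#' Precompute and cache edge adjacency on a mesh
#'
#' Silhouette extraction queries edge-to-face adjacency on every pose
#' evaluation; caching it on the mesh makes repeated registration cost
#' evaluations cheap.
#'
#' @param mesh A [tri_mesh()].
#' @return The mesh with an `ef` adjacency field attached.
#' @export
mesh_precompute <- function(mesh) {
  if (is.null(mesh$ef)) mesh$ef <- mesh_edge_faces(mesh)
  mesh
}

#' Edge-to-face adjacency
#'
#' @param mesh A [tri_mesh()].
#' @return List with `edges` (k x 2 vertex indices, a < b) and `faces`
#'   (k x 2 face indices adjacent to each edge; NA when on a boundary).
#' @keywords internal
mesh_edge_faces <- function(mesh) {
  if (!is.null(mesh$ef)) return(mesh$ef)
  f <- mesh$f
  m <- nrow(f)
  ea <- rbind(cbind(f[, 1], f[, 2]), cbind(f[, 2], f[, 3]), cbind(f[, 3], f[, 1]))
  fid <- rep(seq_len(m), 3L)
  a <- pmin(ea[, 1], ea[, 2]); b <- pmax(ea[, 1], ea[, 2])
  o <- order(a, b)
  a <- a[o]; b <- b[o]; fid <- fid[o]
  new_edge <- c(TRUE, a[-1] != a[-length(a)] | b[-1] != b[-length(b)])
  eid <- cumsum(new_edge)
  k <- eid[length(eid)]
  f1 <- rep(NA_integer_, k); f2 <- rep(NA_integer_, k)
  first <- !duplicated(eid)
  f1[eid[first]] <- fid[first]
  # second occurrence (edges appear at most twice in a manifold mesh)
  dup <- duplicated(eid)
  f2[eid[dup]] <- fid[dup]
  list(edges = cbind(a[first], b[first]), faces = cbind(f1, f2))
}

#' Face normals (unnormalised ok per need)
#' @keywords internal
mesh_face_normals <- function(mesh, normalise = TRUE) {
  a <- mesh$v[mesh$f[, 1], , drop = FALSE]
  e1 <- mesh$v[mesh$f[, 2], , drop = FALSE] - a
  e2 <- mesh$v[mesh$f[, 3], , drop = FALSE] - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  if (normalise) n / pmax(sqrt(rowSums(n^2)), 1e-30) else n
}

#' Transform a mesh by a rigid transform
#' @param mesh A [tri_mesh()].
#' @param t A `rigid_transform`.
#' @export
mesh_transform <- function(mesh, t) {
  out <- tri_mesh(rt_apply(t, mesh$v), mesh$f, mesh$fracture)
  out$ef <- mesh$ef   # adjacency is combinatorial; survives rigid motion
  out
}
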