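#' Read a triangle mesh from STL
#'
#' Reads binary or ASCII STL (auto-detected). Vertices are in millimetres, as
#' produced by CT segmentation software. Because STL carries no face
#' attributes, fracture-surface labels are read from an optional sidecar JSON
#' (`<path>.labels.json`, written by [write_mesh()]) listing 1-based
#' fracture-face indices.
#'
#' @param path STL file path.
#' @param labels Optional explicit sidecar path; default `<path>.labels.json`.
#' @return A [tri_mesh()]. Coincident vertices are merged.
#' @export
read_mesh <- function(path, labels = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  header <- readBin(con, "raw", 80L)
  if (length(header) < 80L) {
    close(con)
    stop(sprintf("malformed STL '%s': truncated header at byte %d",
                 path, length(header)))
  }
  ntri_raw <- readBin(con, "raw", 4L)
  close(con)
  ntri <- if (length(ntri_raw) == 4L)
    readBin(ntri_raw, "integer", 1L, size = 4L) else -1L
  expect_bin <- 84 + 50 * as.numeric(ntri)
  is_binary <- length(ntri_raw) == 4L && ntri >= 0 &&
    file.size(path) == expect_bin
  tri <- if (is_binary) read_stl_binary(path, ntri) else read_stl_ascii(path)
  mesh <- index_triangles(tri)
  if (is.null(labels)) labels <- paste0(path, ".labels.json")
  if (file.exists(labels)) {
    idx <- jsonlite::read_json(labels, simplifyVector = TRUE)$fracture_faces
    fr <- rep(FALSE, nrow(mesh$f))
    fr[as.integer(idx)] <- TRUE
    mesh$fracture <- fr
  }
  mesh
}

read_stl_binary <- function(path, ntri) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 84L)
  rec <- readBin(con, "raw", 50L * ntri)
  if (length(rec) != 50L * ntri)
    stop(sprintf("malformed STL '%s': truncated at byte %d",
                 path, 84L + length(rec)))
  rec <- matrix(rec, nrow = 50L)
  vals <- readBin(as.vector(rec[1:48, , drop = FALSE]), "numeric",
                  12L * ntri, size = 4L)
  vals <- matrix(vals, nrow = 12L)
  # rows 4..12 are the three vertices
  t(vals[4:12, , drop = FALSE])
}

read_stl_ascii <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (!length(txt) || !grepl("^\\s*solid", txt[1]))
    stop(sprintf("malformed STL '%s': neither valid binary nor ASCII ('solid' missing at byte 0)", path))
  vl <- grep("^\\s*vertex\\s", txt)
  if (!length(txt) || !any(grepl("endsolid", txt)))
    stop(sprintf("malformed STL '%s': missing 'endsolid' (file truncated near byte %d)",
                 path, sum(nchar(txt)) + length(txt)))
  if (length(vl) %% 3 != 0)
    stop(sprintf("malformed STL '%s': vertex count %d not a multiple of 3",
                 path, length(vl)))
  nums <- vapply(strsplit(trimws(txt[vl]), "\\s+"), function(w)
    as.numeric(w[2:4]), numeric(3))
  # columns of `nums` are vertices in file order; 3 consecutive per facet
  matrix(as.vector(nums), ncol = 9, byrow = TRUE)
}

index_triangles <- function(tri9) {
  ntri <- nrow(tri9)
  pts <- rbind(tri9[, 1:3, drop = FALSE], tri9[, 4:6, drop = FALSE],
               tri9[, 7:9, drop = FALSE])
  key <- paste(sprintf("%.9g", pts[, 1]), sprintf("%.9g", pts[, 2]),
               sprintf("%.9g", pts[, 3]))
  uid <- match(key, unique(key))
  v <- pts[!duplicated(uid), , drop = FALSE]
  f <- matrix(uid, ncol = 3)
  tri_mesh(v, f)
}

# rows-of-numbers JSON field -> numeric matrix (jsonlite may deliver either
# a matrix or a list of row vectors depending on raggedness)
json_matrix <- function(x, nr, nc) {
  if (is.matrix(x)) {
    m <- x
  } else {
    m <- do.call(rbind, lapply(x, as.numeric))
  }
  storage.mode(m) <- "double"
  stopifnot(all(dim(m) == c(nr, nc)))
  m
}

#' Write a triangle mesh to ASCII STL
#'
#' Writes ASCII STL plus, when the mesh has fracture-labelled faces, a
#' sidecar `<path>.labels.json` holding their indices (STL itself cannot
#' carry attributes).
#'
#' @param mesh A [tri_mesh()].
#' @param path Output path.
#' @export
write_mesh <- function(mesh, path) {
  n <- mesh_face_normals(mesh)
  a <- mesh$v[mesh$f[, 1], , drop = FALSE]
  b <- mesh$v[mesh$f[, 2], , drop = FALSE]
  c3 <- mesh$v[mesh$f[, 3], , drop = FALSE]
  fmt <- function(m) sprintf("%.9g %.9g %.9g", m[, 1], m[, 2], m[, 3])
  lines <- c("solid fluororeg",
             as.vector(rbind(
               sprintf("  facet normal %s", fmt(n)),
               "    outer loop",
               sprintf("      vertex %s", fmt(a)),
               sprintf("      vertex %s", fmt(b)),
               sprintf("      vertex %s", fmt(c3)),
               "    endloop",
               "  endfacet")),
             "endsolid fluororeg")
  writeLines(lines, path)
  if (any(mesh$fracture)) {
    jsonlite::write_json(list(fracture_faces = which(mesh$fracture)),
                         paste0(path, ".labels.json"))
  }
  invisible(path)
}

#' Write / read a rigid transform as JSON
#'
#' Serialised as a row-major 4x4 homogeneous matrix at 17 significant digits,
#' so the round trip is lossless to double precision. On read, the rotation
#' block is validated (orthonormal within 1e-6) before acceptance.
#'
#' @param path JSON path.
#' @param t A `rigid_transform`.
#' @export
write_transform <- function(path, t) {
  m <- rt_matrix(t)
  obj <- list(type = "rigid_transform",
              matrix = lapply(seq_len(4), function(i) m[i, ]))
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- json_matrix(obj$matrix, 4, 4)
  rt_from_matrix(m, tol = 1e-6)
}

#' Write / read a C-arm model as JSON
#' @param path JSON path.
#' @param carm A [carm_model()].
#' @export
write_carm <- function(path, carm) {
  obj <- list(sid = carm$sid, pixel_size = carm$pixel_size,
              detector_diameter = carm$detector_diameter,
              image_shape = carm$image_shape,
              principal_point = carm$principal_point)
  if (!is.null(carm$distortion))
    obj$distortion <- list(coefficients = carm$distortion$coefficients,
                           center = carm$distortion$center)
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' @rdname write_carm
#' @export
read_carm <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- if (!is.null(o$distortion))
    radial_distortion(o$distortion$coefficients, o$distortion$center)
  carm_model(sid = o$sid, pixel_size = o$pixel_size,
             detector_diameter = o$detector_diameter,
             image_shape = o$image_shape,
             principal_point = o$principal_point,
             distortion = d)
}

#' Default C-arm configuration
#'
#' The configuration shipped with the package: SID 980 mm, pixel size
#' 0.224 mm, 230 mm image intensifier (a GE OEC Fluorostar-class C-arm).
#' @export
carm_default <- function() {
  read_carm(system.file("extdata", "carm_default.json",
                        package = "fluororeg", mustWork = TRUE))
}

#' Write / read fiducial geometry as JSON
#' @param path JSON path.
#' @param fid A [fiducial_geometry()].
#' @export
write_fiducial <- function(path, fid) {
  jsonlite::write_json(list(
    bead_centers = lapply(seq_len(3), function(i) fid$beads[i, ]),
    pin_tip = fid$pin_tip), path, digits = NA)
  invisible(path)
}

#' @rdname write_fiducial
#' @export
read_fiducial <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  fiducial_geometry(json_matrix(o$bead_centers, 3, 3), as.numeric(o$pin_tip))
}

#' Default registration-tool fiducial geometry
#'
#' Three bead centres and the pin-tip point in the registration-tool frame
#' (which coincides with the pin frame). Shipped in
#' `extdata/fiducial_default.json`.
#' @export
fiducial_default <- function() {
  read_fiducial(system.file("extdata", "fiducial_default.json",
                            package = "fluororeg", mustWork = TRUE))
}

#' Write / read labelled feature detections as JSON
#'
#' The manual pathway: detections produced elsewhere (e.g. clicked by an
#' operator) can be supplied to [estimate_image_pose()] via this format.
#'
#' @param path JSON path.
#' @param det A `feature_detections` object.
#' @export
write_detections <- function(path, det) {
  jsonlite::write_json(list(
    points = lapply(seq_len(nrow(det$points)), function(i) det$points[i, ]),
    labels = det$labels), path, digits = NA)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  feature_detections(matrix(as.numeric(unlist(o$points)), ncol = 2,
                            byrow = TRUE), o$labels)
}

#' Write an image matrix to TIFF or PNG (if the writer package is installed)
#'
#' Images are plain numeric matrices in [0, 1], rows = image v, cols = u.
#' @param image Numeric matrix.
#' @param path Output path ending in .tiff/.tif or .png.
#' @export
write_image <- function(image, path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("package 'png' required to write PNG")
    png::writePNG(pmin(pmax(image, 0), 1), path)
  } else {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("package 'tiff' required to write TIFF")
    tiff::writeTIFF(pmin(pmax(image, 0), 1), path, bits.per.sample = 16L)
  }
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("package 'png' required to read PNG")
    png::readPNG(path)
  } else {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("package 'tiff' required to read TIFF")
    tiff::readTIFF(path)
  }
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img
}
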