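#' Ball-bearing calibration grid model
#'
#' The calibration phantom: metallic ball bearings on a plane at a known,
#' constant pitch in x and y. Defaults are a 22-mm pitch grid of 10-mm
#' bearings; 7 x 7 is the largest square grid at that pitch whose corner
#' beads still fall inside a circular 230-mm intensifier.
#'
#' @param spacing Bead pitch dx = dy (mm).
#' @param bead_diameter Bead diameter (mm).
#' @param n_rows,n_cols Grid extent (>= 3 each for polynomial solvability).
#' @export
bead_grid_model <- function(spacing = 22, bead_diameter = 10,
                            n_rows = 7, n_cols = 7) {
  stopifnot(spacing > bead_diameter / 2, n_rows >= 3, n_cols >= 3)
  structure(list(spacing = spacing, bead_diameter = bead_diameter,
                 n_rows = as.integer(n_rows), n_cols = as.integer(n_cols)),
            class = "bead_grid_model")
}

#' Segment calibration beads in a grid image
#'
#' Otsu threshold, connected-component labelling, intensity-weighted
#' centroid per component. Components smaller than a disk of `min_radius_px`
#' are discarded as noise.
#'
#' @param image Numeric matrix in [0, 1].
#' @param expected_count Beads expected (grid rows x cols).
#' @param min_radius_px Minimum plausible bead radius (default 4).
#' @return n x 2 matrix of centroids (u, v) px; errors with a
#'   calibration-coverage message if the count does not match.
#' @export
segment_beads <- function(image, expected_count, min_radius_px = 4) {
  if (max(image) - min(image) < 1e-6)
    stop(sprintf("calibration coverage error: 0 beads detected, expected %d (blank image)",
                 expected_count))
  th <- EBImage::otsu(EBImage::Image(image), range = c(0, 1))
  bw <- image > th
  lab <- EBImage::bwlabel(bw)
  n <- max(lab)
  min_area <- pi * min_radius_px^2
  idx <- which(lab > 0, arr.ind = TRUE)
  labs <- lab[lab > 0]
  cents <- NULL
  for (i in seq_len(n)) {
    sel <- labs == i
    if (sum(sel) < min_area) next
    pix <- idx[sel, , drop = FALSE]
    w <- image[pix] - th
    cents <- rbind(cents, c(sum(pix[, 2] * w), sum(pix[, 1] * w)) / sum(w))
  }
  found <- if (is.null(cents)) 0L else nrow(cents)
  if (found != expected_count) {
    stop(sprintf(paste0("calibration coverage error: %d beads detected, ",
                        "expected %d; check grid placement and exposure"),
                 found, expected_count))
  }
  unname(cents)
}

#' Match detected bead centroids to the ideal grid lattice
#'
#' The ideal lattice has pitch `spacing / pixel_size` px (unit magnification:
#' the grid lies on the detector), centred at the principal point. Detected
#' centroids are similarity pre-aligned (translation by centroid matching
#' plus an in-plane rotation search) and then assigned to their nearest
#' ideal node; the assignment must be bijective.
#'
#' @param centroids n x 2 detected centroids (px).
#' @param grid A [bead_grid_model()].
#' @param carm A [carm_model()] supplying nominal pixel size and principal
#'   point.
#' @return data.frame with detected (det_u, det_v), ideal (ideal_u, ideal_v)
#'   and lattice indices (row, col).
#' @export
match_grid <- function(centroids, grid, carm) {
  cents <- as_points2(centroids)
  if (nrow(cents) < 9) stop("matching error: need at least 9 centroids")
  lat <- grid_lattice_px(grid, carm)
  # grid_lattice_px expands u (columns) fastest
  cols <- rep(seq_len(grid$n_cols), times = grid$n_rows)
  rows <- rep(seq_len(grid$n_rows), each = grid$n_cols)
  ctr_d <- colMeans(cents)
  ctr_i <- colMeans(lat)
  best <- NULL
  for (ang in seq(-10, 10, by = 0.25) * pi / 180) {
    Rm <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
    al <- sweep(sweep(cents, 2, ctr_d) %*% t(Rm), 2, ctr_i, "+")
    dd <- outer(al[, 1], lat[, 1], "-")^2 + outer(al[, 2], lat[, 2], "-")^2
    nn <- max.col(-dd, ties.method = "first")
    cost <- mean(sqrt(dd[cbind(seq_len(nrow(al)), nn)]))
    if (is.null(best) || cost < best$cost) best <- list(nn = nn, cost = cost)
  }
  nn <- best$nn
  if (anyDuplicated(nn))
    stop("matching error: ambiguous assignment (two detections claim one grid node)")
  data.frame(det_u = cents[, 1], det_v = cents[, 2],
             ideal_u = lat[nn, 1], ideal_v = lat[nn, 2],
             row = rows[nn], col = cols[nn])
}

#' Fit a global polynomial distortion correction
#'
#' Least-squares bivariate polynomial (all monomials of total degree <=
#' `degree`) mapping distorted detector coordinates to corrected ones, one
#' polynomial per output coordinate; the global correction can then be
#' evaluated anywhere on the detector with [correct_points()].
#'
#' @param correspondences data.frame from [match_grid()] (or with the same
#'   det_/ideal_ columns).
#' @param degree Total polynomial degree (2-5; default 3).
#' @return A `polynomial_correction` with `fit_rms` (px) and per-bead
#'   `residuals`.
#' @export
fit_distortion <- function(correspondences, degree = 3) {
  stopifnot(degree >= 2, degree <= 5)
  cc <- correspondences
  n_coef <- (degree + 1) * (degree + 2) / 2
  if (nrow(cc) < n_coef)
    stop(sprintf("fit error: %d correspondences for %d coefficients",
                 nrow(cc), n_coef))
  # normalise for conditioning
  su <- stats::sd(cc$det_u); sv <- stats::sd(cc$det_v)
  mu <- mean(cc$det_u); mv <- mean(cc$det_v)
  X <- poly2d_design((cc$det_u - mu) / su, (cc$det_v - mv) / sv, degree)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("fit error: rank-deficient design (collinear beads?)")
  cu <- qr.coef(qrX, cc$ideal_u)
  cv <- qr.coef(qrX, cc$ideal_v)
  pred <- cbind(X %*% cu, X %*% cv)
  res <- sqrt((pred[, 1] - cc$ideal_u)^2 + (pred[, 2] - cc$ideal_v)^2)
  structure(list(degree = degree, coeffs_u = cu, coeffs_v = cv,
                 norm = c(mu = mu, mv = mv, su = su, sv = sv),
                 fit_rms = sqrt(mean(res^2)), residuals = res),
            class = "polynomial_correction")
}

poly2d_design <- function(x, y, degree) {
  cols <- list()
  for (d in 0:degree) for (i in 0:d) {
    cols[[length(cols) + 1L]] <- x^(d - i) * y^i
  }
  do.call(cbind, cols)
}

#' Apply a polynomial correction to pixel coordinates
#' @param corr A `polynomial_correction`.
#' @param points_px m x 2 matrix of distorted coordinates.
#' @export
correct_points <- function(corr, points_px) {
  p <- as_points2(points_px)
  X <- poly2d_design((p[, 1] - corr$norm["mu"]) / corr$norm["su"],
                     (p[, 2] - corr$norm["mv"]) / corr$norm["sv"],
                     corr$degree)
  cbind(as.numeric(X %*% corr$coeffs_u), as.numeric(X %*% corr$coeffs_v))
}

#' Estimate the intensifier pixel size from matched grid beads
#'
#' Uses the lattice adjacency recovered by [match_grid()]: the mean pixel
#' distance between 4-neighbour bead pairs is the observed pitch; under the
#' unit-magnification assumption (grid on the detector), pixel size =
#' spacing / pitch.
#'
#' @param correspondences data.frame from [match_grid()].
#' @param grid A [bead_grid_model()].
#' @param correction Optional `polynomial_correction` applied to the
#'   detected centroids first (pass the fitted correction only if its
#'   target lattice used the true pixel size; see details in the vignette).
#' @return Estimated pixel size (mm/px).
#' @export
estimate_pixel_size <- function(correspondences, grid, correction = NULL) {
  cc <- correspondences
  if (length(unique(cc$row)) < 2 || length(unique(cc$col)) < 2)
    stop("estimation error: fewer than 2 beads per axis")
  det <- cbind(cc$det_u, cc$det_v)
  if (!is.null(correction)) det <- correct_points(correction, det)
  key <- function(r, c) paste(r, c)
  lut <- stats::setNames(seq_len(nrow(cc)), key(cc$row, cc$col))
  pitches <- c()
  for (i in seq_len(nrow(cc))) {
    for (nb in list(c(0, 1), c(1, 0))) {
      j <- lut[key(cc$row[i] + nb[1], cc$col[i] + nb[2])]
      if (!is.na(j))
        pitches <- c(pitches, sqrt(sum((det[j, ] - det[i, ])^2)))
    }
  }
  grid$spacing / mean(pitches)
}

#' Full C-arm calibration from one grid image
#'
#' Segments the beads, matches them to the ideal lattice, fits the
#' polynomial distortion correction and estimates the pixel size. The
#' quality metric is a hold-out residual: the correction refitted on the
#' interior beads is evaluated on the border ring.
#'
#' @param image Calibration image (matrix in [0, 1]).
#' @param grid A [bead_grid_model()].
#' @param carm Nominal [carm_model()].
#' @param degree Polynomial degree (default 3).
#' @return A `calibration_result`: `correction`, `pixel_size_estimate`,
#'   `residuals`, `holdout_rms`, `correspondences`.
#' @export
calibrate_carm <- function(image, grid, carm, degree = 3) {
  cents <- segment_beads(image, grid$n_rows * grid$n_cols)
  cc <- match_grid(cents, grid, carm)
  corr <- fit_distortion(cc, degree)
  ps <- estimate_pixel_size(cc, grid)
  border <- cc$row %in% c(1, grid$n_rows) | cc$col %in% c(1, grid$n_cols)
  hold <- NA_real_
  if (sum(!border) >= (degree + 1) * (degree + 2) / 2) {
    corr_in <- fit_distortion(cc[!border, ], degree)
    pred <- correct_points(corr_in, cbind(cc$det_u, cc$det_v)[border, ])
    hold <- sqrt(mean((pred[, 1] - cc$ideal_u[border])^2 +
                      (pred[, 2] - cc$ideal_v[border])^2))
  }
  structure(list(correction = corr, pixel_size_estimate = ps,
                 residuals = corr$residuals, holdout_rms = hold,
                 correspondences = cc),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("calibration_result: pixel size %.4f mm/px, fit RMS %.3f px, hold-out RMS %.3f px\n",
              x$pixel_size_estimate, x$correction$fit_rms, x$holdout_rms))
  invisible(x)
}

#' Write / read a calibration result as JSON
#' @param path JSON path.
#' @param cal A `calibration_result`.
#' @export
write_calibration <- function(path, cal) {
  jsonlite::write_json(list(
    degree = cal$correction$degree,
    coeffs_u = cal$correction$coeffs_u,
    coeffs_v = cal$correction$coeffs_v,
    norm = as.list(cal$correction$norm),
    fit_rms = cal$correction$fit_rms,
    pixel_size_estimate = cal$pixel_size_estimate,
    holdout_rms = cal$holdout_rms), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  corr <- structure(list(degree = o$degree,
                         coeffs_u = as.numeric(o$coeffs_u),
                         coeffs_v = as.numeric(o$coeffs_v),
                         norm = c(mu = o$norm$mu, mv = o$norm$mv,
                                  su = o$norm$su, sv = o$norm$sv),
                         fit_rms = o$fit_rms, residuals = NULL),
                    class = "polynomial_correction")
  structure(list(correction = corr, pixel_size_estimate = o$pixel_size_estimate,
                 residuals = NULL, holdout_rms = o$holdout_rms,
                 correspondences = NULL),
            class = "calibration_result")
}
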