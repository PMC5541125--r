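#' Rigid transforms (SE(3))
#'
#' A `rigid_transform` is the universal pose currency of the package: a 3x3
#' rotation matrix plus a translation in millimetres, acting as
#' `y = R x + t`. All homogeneous transforms in the registration chain
#' (pin-to-fragment, view poses, desired reduction poses) are stored this way.
#'
#' @param rotation 3x3 orthonormal matrix with det +1.
#' @param translation length-3 numeric vector (mm).
#' @return An object of class `rigid_transform` with elements `R` and `t`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (abs(det(rotation) - 1) > 1e-6 ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-6) {
    stop("rotation is not a proper orthonormal matrix (det=+1, R'R=I)")
  }
  structure(list(R = rotation, t = translation), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform\n")
  m <- rt_matrix(x)
  print(round(m, 6))
  invisible(x)
}

#' Identity transform
#' @return The identity `rigid_transform`.
#' @export
rt_identity <- function() rigid_transform()

#' Compose two rigid transforms
#'
#' Returns the transform mapping `x` to `a(b(x))`, i.e. matrix product `A B`
#' of the homogeneous 4x4 representations.
#'
#' @param a,b `rigid_transform` objects.
#' @export
rt_compose <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform"), inherits(b, "rigid_transform"))
  structure(list(R = a$R %*% b$R, t = as.numeric(a$R %*% b$t + a$t)),
            class = "rigid_transform")
}

#' Invert a rigid transform
#' @param t A `rigid_transform`.
#' @export
rt_invert <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  Rt <- t(t$R)
  structure(list(R = Rt, t = as.numeric(-Rt %*% t$t)),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#'
#' @param t A `rigid_transform`.
#' @param x Either a length-3 vector or an n x 3 matrix of points (mm).
#' @return Points of the same shape, transformed.
#' @export
rt_apply <- function(t, x) {
  stopifnot(inherits(t, "rigid_transform"))
  if (is.null(dim(x))) {
    as.numeric(t$R %*% as.numeric(x) + t$t)
  } else {
    sweep(x %*% t(t$R), 2, t$t, "+")
  }
}

#' Homogeneous 4x4 matrix of a rigid transform
#' @param t A `rigid_transform`.
#' @export
rt_matrix <- function(t) {
  m <- diag(4)
  m[1:3, 1:3] <- t$R
  m[1:3, 4] <- t$t
  m
}

#' Rigid transform from a homogeneous 4x4 matrix
#'
#' @param m 4x4 matrix with a valid rotation block and bottom row (0,0,0,1).
#' @param tol Orthonormality tolerance (default 1e-6).
#' @export
rt_from_matrix <- function(m, tol = 1e-6) {
  m <- as.matrix(m)
  stopifnot(all(dim(m) == c(4L, 4L)))
  R <- m[1:3, 1:3]
  if (max(abs(m[4, ] - c(0, 0, 0, 1))) > tol)
    stop("bottom row of homogeneous matrix is not (0,0,0,1)")
  dev <- max(abs(det(R) - 1), max(abs(crossprod(R) - diag(3))))
  if (dev > tol)
    stop("rotation block violates orthonormality beyond tolerance")
  if (dev > 1e-12) {
    # re-orthonormalise a small residual; exact inputs pass through bitwise
    s <- svd(R)
    R <- s$u %*% t(s$v)
  }
  rigid_transform(R, m[1:3, 4])
}

#' Rotation matrix from a rotation vector (axis-angle)
#'
#' Rodrigues' formula; the vector's direction is the axis and its norm the
#' angle in radians.
#'
#' @param w length-3 rotation vector (radians).
#' @export
rot_from_vec <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3) + skew3(w))
  k <- w / th
  K <- skew3(k)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rotation vector (axis-angle) from a rotation matrix
#' @param R 3x3 rotation matrix.
#' @return length-3 rotation vector, angle in radians in [0, pi].
#' @export
rot_to_vec <- function(R) {
  ca <- (sum(diag(R)) - 1) / 2
  ca <- min(1, max(-1, ca))
  th <- acos(ca)
  if (th < 1e-9) {
    c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / 2
  } else if (th > pi - 1e-6) {
    # near pi: extract axis from R + I
    B <- (R + diag(3)) / 2
    ax <- sqrt(pmax(diag(B), 0))
    # fix signs using off-diagonals
    i <- which.max(ax)
    s <- c(1, 1, 1)
    for (j in seq_len(3)) if (j != i) s[j] <- sign(B[i, j] + (B[i, j] == 0))
    ax <- ax * s * sign(ax[i] + (ax[i] == 0))
    th * ax / sqrt(sum(ax^2))
  } else {
    th / (2 * sin(th)) *
      c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  }
}

#' Geodesic angle between two rotations
#' @param Ra,Rb 3x3 rotation matrices.
#' @return Angle in degrees.
#' @export
rotation_angle_deg <- function(Ra, Rb = diag(3)) {
  ca <- (sum(diag(crossprod(Rb, Ra))) - 1) / 2
  acos(min(1, max(-1, ca))) * 180 / pi
}

skew3 <- function(w) {
  matrix(c(0, w[3], -w[2],
           -w[3], 0, w[1],
           w[2], -w[1], 0), 3, 3)
}

#' Small-motion update of a pose
#'
#' Left-multiplies `pose` by the rigid motion with rotation vector
#' `d[1:3]` (radians) and translation `d[4:6]` (mm). Used as the local
#' parameterisation of all pose optimisers in the package.
#'
#' @param pose A `rigid_transform`.
#' @param d length-6 numeric (wx, wy, wz, tx, ty, tz).
#' @export
rt_update <- function(pose, d) {
  inc <- rigid_transform(rot_from_vec(d[1:3]), d[4:6])
  rt_compose(inc, pose)
}

#' Small-motion update anchored at a reference point
#'
#' Like [rt_update()], but the rotation increment acts about `center`
#' (world frame) instead of the world origin, so rotation and translation
#' magnitudes stay interpretable for objects far from the origin.
#'
#' @param pose A `rigid_transform`.
#' @param d length-6 numeric (wx, wy, wz, tx, ty, tz), radians and mm.
#' @param center length-3 anchor point in the world frame.
#' @export
rt_update_about <- function(pose, d, center) {
  R <- rot_from_vec(d[1:3])
  inc <- rigid_transform(R, d[4:6] + center - as.numeric(R %*% center))
  rt_compose(inc, pose)
}

#' Distance between two poses
#'
#' @param a,b `rigid_transform` objects.
#' @return Named vector `c(trans = mm, rot = degrees)`: norm of the
#'   translation difference and geodesic rotation angle.
#' @export
rt_distance <- function(a, b) {
  c(trans = sqrt(sum((a$t - b$t)^2)),
    rot = rotation_angle_deg(a$R, b$R))
}

#' Random rigid transform (for tests and search)
#'
#' @param max_angle_deg Maximum rotation angle (degrees).
#' @param max_trans Maximum translation magnitude (mm).
#' @export
rt_random <- function(max_angle_deg = 180, max_trans = 100) {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, max_angle_deg * pi / 180)
  tr <- stats::runif(3, -1, 1) * max_trans
  rigid_transform(rot_from_vec(ax * th), tr)
}
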