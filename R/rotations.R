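# Small rotation / homogeneous-transform toolkit used throughout the package.
# All angles are degrees at the API surface; radians internally.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Elementary rotation matrices
#'
#' Right-handed rotations about the coordinate axes, angle in degrees.
#'
#' @param theta rotation angle, degrees.
#' @return 3x3 rotation matrix.
#' @export
rot_x <- function(theta) {
  a <- deg2rad(theta); c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}

#' @rdname rot_x
#' @export
rot_y <- function(theta) {
  a <- deg2rad(theta); c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}

#' @rdname rot_x
#' @export
rot_z <- function(theta) {
  a <- deg2rad(theta); c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' Build a 4x4 homogeneous rigid transform
#'
#' @param R 3x3 rotation matrix.
#' @param t length-3 translation, mm.
#' @return 4x4 homogeneous matrix.
#' @export
homogeneous <- function(R = diag(3), t = c(0, 0, 0)) {
  T <- diag(4)
  T[1:3, 1:3] <- R
  T[1:3, 4] <- t
  T
}

#' Invert a rigid transform
#'
#' Uses the closed form for rigid transforms (transpose + reprojected
#' translation) rather than a general matrix inverse.
#'
#' @param T 4x4 rigid transform.
#' @return the inverse transform.
#' @export
invert_rigid <- function(T) {
  R <- T[1:3, 1:3]
  homogeneous(t(R), -crossprod(R, T[1:3, 4]))
}

#' Apply a rigid transform to 3D points
#'
#' @param T 4x4 rigid transform.
#' @param pts n x 3 matrix (or length-3 vector) of points.
#' @return transformed points, same shape as input.
#' @export
transform_points <- function(T, pts) {
  vec <- is.null(dim(pts))
  if (vec) pts <- matrix(pts, 1, 3)
  out <- pts %*% t(T[1:3, 1:3])
  out <- sweep(out, 2, T[1:3, 4], "+")
  if (vec) drop(out) else out
}

# Rotation about an arbitrary pivot point (world coords), as a 4x4 transform.
rotation_about_point <- function(R, pivot) {
  homogeneous(R, as.numeric(pivot - R %*% pivot))
}

#' Check that a 3x3 matrix is a proper rotation
#'
#' @param R 3x3 matrix.
#' @param tol tolerance on orthonormality and determinant.
#' @return TRUE/FALSE.
#' @export
is_rotation <- function(R, tol = 1e-6) {
  all(dim(R) == c(3, 3)) &&
    max(abs(crossprod(R) - diag(3))) <= tol &&
    abs(det(R) - 1) <= tol
}

#' Project a near-rotation matrix onto SO(3)
#'
#' Nearest proper rotation in the Frobenius sense, via SVD with a
#' determinant correction.
#'
#' @param M 3x3 matrix close to a rotation.
#' @return 3x3 proper rotation matrix.
#' @export
orthonormalize_rotation <- function(M) {
  sv <- svd(M)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

#' Convert a rotation matrix to a unit quaternion
#'
#' Returns (w, x, y, z) with w >= 0 unless sign continuity is managed by the
#' caller. Uses Shepperd's method for numerical stability.
#'
#' @param R 3x3 rotation matrix.
#' @return length-4 unit quaternion (w, x, y, z).
#' @export
mat2quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s,
           (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s,
           0.25 * s,
           (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s,
           (R[1, 2] + R[2, 1]) / s,
           0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s,
           (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s,
           0.25 * s)
  }
  q / sqrt(sum(q^2))
}

#' Convert a unit quaternion to a rotation matrix
#'
#' @param q length-4 quaternion (w, x, y, z); renormalized internally.
#' @return 3x3 rotation matrix.
#' @export
quat2mat <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z),  2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2),  2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x),  1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

#' Intrinsic z-y-x Euler decomposition
#'
#' Decomposes R = Rz(gamma) Ry(beta) Rx(alpha) (rotation about z first, then
#' the rotated y, then the rotated x). Near the gimbal singularity
#' (|beta| = 90 deg) alpha is pinned to zero and gamma absorbs the remaining
#' in-plane rotation.
#'
#' @param R 3x3 rotation matrix.
#' @param gimbal_tol_deg width of the band around |beta| = 90 deg flagged as
#'   gimbal-proximate.
#' @return list with `z`, `y`, `x` angles in degrees (in (-180, 180]) and a
#'   logical `gimbal` flag.
#' @export
euler_zyx <- function(R, gimbal_tol_deg = 0.5) {
  sy <- -R[3, 1]
  sy <- max(-1, min(1, sy))
  beta <- asin(sy)
  near_gimbal <- abs(abs(rad2deg(beta)) - 90) < gimbal_tol_deg
  if (abs(abs(sy) - 1) < 1e-12) {
    # exact gimbal: alpha := 0, gamma carries the rest
    alpha <- 0
    gamma <- atan2(-R[1, 2], R[2, 2])
  } else {
    gamma <- atan2(R[2, 1], R[1, 1])
    alpha <- atan2(R[3, 2], R[3, 3])
  }
  list(z = rad2deg(gamma), y = rad2deg(beta), x = rad2deg(alpha),
       gimbal = near_gimbal)
}

#' Recompose an intrinsic z-y-x Euler triple
#'
#' @param z,y,x angles in degrees.
#' @return 3x3 rotation matrix Rz(z) Ry(y) Rx(x).
#' @export
euler_zyx_to_mat <- function(z, y, x) {
  rot_z(z) %*% rot_y(y) %*% rot_x(x)
}
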