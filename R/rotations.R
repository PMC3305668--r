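# Rotation and rigid-pose utilities.
#
# Rotations are stored as 3x3 proper orthonormal matrices; unit quaternions
# (w, x, y, z) and axis-angle vectors are offered for serialization and for
# the optimizer's local parameterization.

#' Rigid pose mapping the nail frame into the camera frame
#'
#' The camera frame is right handed with the X-ray point source at the origin
#' and +z toward the detector. A pose transforms nail-frame coordinates `p` to
#' camera-frame coordinates `R p + t`.
#'
#' @param rotation 3x3 proper rotation matrix (orthonormal, det +1).
#' @param translation_mm length-3 numeric, translation in mm.
#' @return An object of class `nail_pose`.
#' @export
nail_pose <- function(rotation = diag(3), translation_mm = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation_mm) == 3L)
  err <- max(abs(crossprod(rotation) - diag(3)))
  if (err > 1e-9 || abs(det(rotation) - 1) > 1e-9) {
    stop("rotation must be orthonormal with determinant +1 (within 1e-9)")
  }
  structure(
    list(rotation = rotation, translation_mm = as.numeric(translation_mm)),
    class = "nail_pose"
  )
}

#' @export
print.nail_pose <- function(x, ...) {
  q <- rotation_to_quaternion(x$rotation)
  cat(sprintf(
    "<nail_pose> q = [%.4f %.4f %.4f %.4f], t = [%.2f %.2f %.2f] mm\n",
    q[1], q[2], q[3], q[4],
    x$translation_mm[1], x$translation_mm[2], x$translation_mm[3]
  ))
  invisible(x)
}

# Apply a pose to one point or to the rows of an n x 3 matrix.
pose_apply <- function(pose, p) {
  if (is.matrix(p)) {
    sweep(p %*% t(pose$rotation), 2, pose$translation_mm, "+")
  } else {
    as.numeric(pose$rotation %*% p + pose$translation_mm)
  }
}

pose_compose <- function(outer, inner) {
  nail_pose(
    rotation = outer$rotation %*% inner$rotation,
    translation_mm = as.numeric(outer$rotation %*% inner$translation_mm) +
      outer$translation_mm
  )
}

#' Rotation matrix from an axis-angle vector
#'
#' Rodrigues' formula; the vector's norm is the rotation angle in radians.
#'
#' @param w length-3 numeric axis-angle vector.
#' @return 3x3 rotation matrix.
#' @export
axis_angle_to_rotation <- function(w) {
  theta <- sqrt(sum(w^2))
  if (theta < 1e-300) return(diag(3))
  k <- w / theta
  K <- skew3(k)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Axis-angle vector of a rotation matrix
#' @param R 3x3 rotation matrix.
#' @return length-3 axis-angle vector (angle in \[0, pi\]).
#' @export
rotation_to_axis_angle <- function(R) {
  q <- rotation_to_quaternion(R)
  v <- q[2:4]
  s <- sqrt(sum(v^2))
  if (s < 1e-15) return(c(0, 0, 0))
  2 * atan2(s, q[1]) * v / s
}

#' Unit quaternion (w, x, y, z) of a rotation matrix
#' @param R 3x3 rotation matrix.
#' @return length-4 numeric with non-negative scalar part.
#' @export
rotation_to_quaternion <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s, (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
           (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
           0.25 * s, (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  if (q[1] < 0) q <- -q
  q / sqrt(sum(q^2))
}

#' Rotation matrix of a unit quaternion (w, x, y, z)
#' @param q length-4 numeric quaternion; normalized internally.
#' @return 3x3 rotation matrix.
#' @export
quaternion_to_rotation <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

skew3 <- function(v) {
  matrix(c(0, -v[3], v[2],
           v[3], 0, -v[1],
           -v[2], v[1], 0), 3, 3, byrow = TRUE)
}

unit3 <- function(v) v / sqrt(sum(v^2))

# Any unit vector orthogonal to v.
orthonormal_to <- function(v) {
  v <- unit3(v)
  u <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unit3(u - sum(u * v) * v)
}

# Angle in degrees between two directions treated as undirected lines.
line_angle_deg <- function(a, b) {
  a <- unit3(a); b <- unit3(b)
  d <- min(1, abs(sum(a * b)))
  acos(d) * 180 / pi
}
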