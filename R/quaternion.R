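#' Quaternion utilities
#'
#' Head orientation is stored as unit quaternions in scalar-first order
#' (w, x, y, z), one row per sample. A quaternion q rotates a head-frame
#' vector v into the world frame via q v q*. All angular differences between
#' orientations are geodesic (shortest-arc) rotation angles.
#'
#' @name quaternion
#' @keywords internal
NULL

#' Normalize quaternions to unit norm
#'
#' @param q numeric matrix n x 4 (w, x, y, z) or length-4 vector.
#' @return matrix of unit quaternions, same shape.
#' @export
quat_normalize <- function(q) {
  q <- quat_mat(q)
  n <- sqrt(rowSums(q^2))
  if (any(n == 0)) stop("zero-norm quaternion cannot be normalized")
  q / n
}

quat_mat <- function(q) {
  if (is.null(dim(q))) q <- matrix(q, ncol = 4L)
  stopifnot(ncol(q) == 4L)
  q
}

#' Hamilton product of quaternions
#'
#' Row-wise product; either argument may be a single quaternion which is
#' recycled.
#' @param a,b quaternion matrices (n x 4) or length-4 vectors.
#' @return n x 4 matrix a * b.
#' @export
quat_multiply <- function(a, b) {
  a <- quat_mat(a); b <- quat_mat(b)
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  w <- a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4]
  x <- a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3]
  y <- a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2]
  z <- a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1]
  cbind(w = w, x = x, y = y, z = z)
}

#' Quaternion conjugate
#' @param q quaternion matrix or vector.
#' @return conjugate, same shape as matrix.
#' @export
quat_conjugate <- function(q) {
  q <- quat_mat(q)
  q[, 2:4] <- -q[, 2:4]
  q
}

#' Rotate 3D vectors by quaternions
#'
#' @param q unit quaternion(s), n x 4 or length 4.
#' @param v 3D vector(s), n x 3 or length 3.
#' @return n x 3 matrix of rotated vectors.
#' @export
quat_rotate <- function(q, v) {
  q <- quat_mat(q)
  if (is.null(dim(v))) v <- matrix(v, ncol = 3L)
  if (nrow(q) == 1L && nrow(v) > 1L) q <- q[rep(1L, nrow(v)), , drop = FALSE]
  if (nrow(v) == 1L && nrow(q) > 1L) v <- v[rep(1L, nrow(q)), , drop = FALSE]
  # v' = v + 2 q_vec x (q_vec x v + w v), the standard expansion
  qv <- q[, 2:4, drop = FALSE]
  w <- q[, 1]
  t1 <- 2 * cross3(qv, v)
  v + w * t1 + cross3(qv, t1)
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Quaternion from axis and angle
#' @param axis length-3 axis (normalized internally).
#' @param angle rotation angle in radians.
#' @return 1 x 4 unit quaternion (or n x 4 for vector angle).
#' @export
quat_from_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  cbind(w = cos(angle / 2),
        x = axis[1] * sin(angle / 2),
        y = axis[2] * sin(angle / 2),
        z = axis[3] * sin(angle / 2))
}

#' Geodesic angle between successive or paired orientations
#'
#' The minimal rotation angle taking one orientation to the other,
#' in radians, insensitive to the q / -q sign ambiguity.
#' @param a,b unit quaternion matrices, same number of rows.
#' @return numeric vector of angles in [0, pi].
#' @export
quat_angle <- function(a, b) {
  a <- quat_mat(a); b <- quat_mat(b)
  d <- abs(rowSums(a * b))
  d <- pmin(d, 1)
  2 * acos(d)
}

#' Quaternion from a rotation matrix
#' @param R 3 x 3 rotation matrix (columns are the frame axes in world
#'   coordinates).
#' @return 1 x 4 unit quaternion.
#' @export
quat_from_matrix <- function(R) {
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
  quat_normalize(matrix(q, ncol = 4L))
}

#' Yaw-pitch composed quaternion
#'
#' Builds an orientation by first pitching about the head x axis, then
#' yawing about the world z axis (both in radians). With zero arguments the
#' head frame coincides with the world frame (beak along +y).
#' @param yaw rotation about world z (counterclockwise from +y beak).
#' @param pitch rotation about head x axis (positive pitches the beak up).
#' @return n x 4 quaternion matrix.
#' @export
quat_yaw_pitch <- function(yaw, pitch = 0) {
  n <- max(length(yaw), length(pitch))
  yaw <- rep_len(yaw, n); pitch <- rep_len(pitch, n)
  qz <- cbind(cos(yaw / 2), 0, 0, sin(yaw / 2))
  qx <- cbind(cos(pitch / 2), sin(pitch / 2), 0, 0)
  quat_multiply(qz, qx)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Angle between vectors, in degrees
#' @param a,b n x 3 matrices or length-3 vectors.
#' @return angles in [0, 180] degrees.
#' @export
angle_between_deg <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 3L)
  if (is.null(dim(b))) b <- matrix(b, ncol = 3L)
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  num <- rowSums(a * b)
  den <- sqrt(rowSums(a^2) * rowSums(b^2))
  cosang <- ifelse(den > 0, num / den, 1)
  rad2deg(acos(pmin(1, pmax(-1, cosang))))
}
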