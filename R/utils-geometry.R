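# Small 3D geometry helpers shared across the package.  All positions are in
# millimetres, all internal angles in radians; degrees appear only at user
# interfaces.

vnorm <- function(v) sqrt(sum(v * v))

normalize <- function(v, what = "vector") {
  n <- vnorm(v)
  if (n < 1e-12) {
    stop("cannot normalize near-zero ", what, " (norm = ", format(n), ")")
  }
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Signed angle from `u` to `v` about `axis`
#'
#' Both vectors are projected onto the plane perpendicular to `axis`; the
#' returned angle is in (-pi, pi], positive for a right-handed rotation about
#' `axis`.
#' @noRd
signed_angle <- function(u, v, axis) {
  ax <- normalize(axis, "rotation axis")
  up <- u - sum(u * ax) * ax
  vp <- v - sum(v * ax) * ax
  if (vnorm(up) < 1e-12 || vnorm(vp) < 1e-12) {
    stop("signed_angle: vector parallel to the rotation axis")
  }
  atan2(sum(cross3(up, vp) * ax), sum(up * vp))
}

#' Rodrigues rotation of points about an axis through a center
#'
#' @param pts n x 3 matrix (or length-3 vector) of points.
#' @param axis rotation axis (need not be unit).
#' @param angle rotation angle in radians.
#' @param center point on the rotation axis.
#' @return rotated points, same shape as input.
#' @noRd
rotate_about_axis <- function(pts, axis, angle, center = c(0, 0, 0)) {
  vec_in <- is.null(dim(pts))
  if (vec_in) pts <- matrix(pts, nrow = 1L)
  k <- normalize(axis, "rotation axis")
  p <- sweep(pts, 2L, center)
  ca <- cos(angle); sa <- sin(angle)
  kx <- p[, 1L] * k[1L] + p[, 2L] * k[2L] + p[, 3L] * k[3L]
  crx <- cbind(k[2L] * p[, 3L] - k[3L] * p[, 2L],
               k[3L] * p[, 1L] - k[1L] * p[, 3L],
               k[1L] * p[, 2L] - k[2L] * p[, 1L])
  out <- p * ca + crx * sa + outer(kx * (1 - ca), k)
  out <- sweep(out, 2L, -center)
  if (vec_in) out[1L, ] else out
}

rotation_matrix_axis <- function(axis, angle) {
  k <- normalize(axis)
  K <- matrix(c(0, k[3L], -k[2L], -k[3L], 0, k[1L], k[2L], -k[1L], 0), 3L, 3L)
  diag(3L) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Check that a 3x3 matrix is a proper rotation
#' @noRd
is_rotation <- function(R, tol = 1e-9) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) &&
    max(abs(crossprod(R) - diag(3L))) < tol &&
    abs(det(R) - 1) < tol
}

#' Homogeneous 4x4 rigid transform from rotation and translation
#' @noRd
homog <- function(R, t) {
  T <- diag(4L)
  T[1:3, 1:3] <- R
  T[1:3, 4L] <- t
  T
}

apply_homog <- function(T, pts) {
  vec_in <- is.null(dim(pts))
  if (vec_in) pts <- matrix(pts, nrow = 1L)
  out <- pts %*% t(T[1:3, 1:3]) + matrix(T[1:3, 4L], nrow(pts), 3L, byrow = TRUE)
  if (vec_in) out[1L, ] else out
}

invert_homog <- function(T) {
  R <- T[1:3, 1:3]
  homog(t(R), -t(R) %*% T[1:3, 4L])
}

#' Closest points between two 3D lines
#'
#' Lines are given as point + direction.  Returns the feet of the common
#' normal (`q1` on line 1, `q2` on line 2), the gap between them, and whether
#' the directions are parallel at tolerance `par_tol`.
#' @noRd
line_line_closest <- function(p1, d1, p2, d2, par_tol = 1e-9) {
  d1 <- normalize(d1); d2 <- normalize(d2)
  cr <- cross3(d1, d2)
  if (vnorm(cr) < par_tol) {
    return(list(parallel = TRUE, q1 = p1, q2 = p2, gap = NA_real_))
  }
  b <- sum(d1 * d2)
  w0 <- p1 - p2
  denom <- 1 - b * b
  sc <- (b * sum(d2 * w0) - sum(d1 * w0)) / denom
  tc <- (sum(d2 * w0) - b * sum(d1 * w0)) / denom
  q1 <- p1 + sc * d1
  q2 <- p2 + tc * d2
  list(parallel = FALSE, q1 = q1, q2 = q2, gap = vnorm(q1 - q2))
}
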