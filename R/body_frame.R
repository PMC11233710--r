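#' Fly body coordinate system from thorax and wing-hinge landmarks
#'
#' Constructs the right-handed body coordinate system of a fly.  The origin
#' is the posterior scutellum apex (ThAp).  The initial y direction runs from
#' the right to the left wing hinge.  Because the wing hinges sit ventrally
#' relative to the ThAp, the vector from the ThAp to the wing-hinge midpoint
#' is skewed out of the horizontal plane; it is de-skewed by reflecting it
#' across the plane whose normal is `c x y0` (with `c` an anteroposterior
#' hint axis, by default the global x axis) and averaging with the original
#' -- the mean of a vector and its mirror image lies in the reflection
#' plane, which removes the dorsoventral tilt.  The y axis is then
#' re-orthogonalized against x (keeping a positive dot product with the
#' initial left-pointing y), and z = x cross y completes the right-handed
#' frame.
#'
#' @param ThAp,lWH,rWH length-3 positions (mm) of the posterior scutellum
#'   apex and the left/right wing hinge.
#' @param anteroposterior length-3 hint for the posterior-to-anterior
#'   direction in the global frame (default: global x axis).
#' @return an object of class `body_frame` with fields `origin`, `x_axis`,
#'   `y_axis`, `z_axis` (unit vectors).
#' @export
compute_body_frame <- function(ThAp, lWH, rWH, anteroposterior = c(1, 0, 0)) {
  ThAp <- as.numeric(ThAp); lWH <- as.numeric(lWH); rWH <- as.numeric(rWH)
  y0 <- lWH - rWH
  if (vnorm(y0) < 1e-9) stop("degenerate landmarks: lWH equals rWH")
  x_skewed <- (rWH + y0 / 2) - ThAp
  if (vnorm(cross3(x_skewed, y0)) < 1e-9 * vnorm(y0) * max(vnorm(x_skewed), 1e-12)) {
    stop("degenerate landmarks: ThAp collinear with the wing-hinge segment")
  }
  cn <- cross3(as.numeric(anteroposterior), y0)
  if (vnorm(cn) < 1e-9) {
    stop("degenerate landmarks: anteroposterior hint parallel to wing-hinge segment")
  }
  n_r <- normalize(cn)
  r <- x_skewed - 2 * sum(x_skewed * n_r) * n_r
  m <- ThAp + x_skewed / 2
  x <- (m + r / 2) - ThAp              # = (x_skewed + r)/2, in-plane component
  x <- normalize(x, "body x axis")
  z_tmp <- cross3(x, y0)
  y <- normalize(cross3(z_tmp, x), "body y axis")
  if (sum(y * y0) < 0) y <- -y
  z <- cross3(x, y)
  structure(list(origin = ThAp, x_axis = x, y_axis = y, z_axis = z),
            class = "body_frame")
}

#' @export
print.body_frame <- function(x, ...) {
  cat("<body_frame> origin", paste(signif(x$origin, 4), collapse = ", "), "mm\n")
  cat("  x:", paste(signif(x$x_axis, 4), collapse = ", "), "\n")
  cat("  y:", paste(signif(x$y_axis, 4), collapse = ", "), "\n")
  cat("  z:", paste(signif(x$z_axis, 4), collapse = ", "), "\n")
  invisible(x)
}

body_frame_rotation <- function(frame) {
  # columns are the body axes expressed in global coordinates
  cbind(frame$x_axis, frame$y_axis, frame$z_axis)
}

#' Transform points between global and body coordinates
#'
#' Rigid transforms; `to_global` is the exact inverse of `to_body`.
#'
#' @param points length-3 vector or n x 3 matrix of positions (mm).
#' @param frame a [compute_body_frame()] result.
#' @return transformed positions, same shape as input.
#' @export
to_body <- function(points, frame) {
  stopifnot(inherits(frame, "body_frame"))
  vec_in <- is.null(dim(points))
  if (vec_in) points <- matrix(points, nrow = 1L)
  out <- sweep(points, 2L, frame$origin) %*% body_frame_rotation(frame)
  if (vec_in) out[1L, ] else out
}

#' @rdname to_body
#' @export
to_global <- function(points, frame) {
  stopifnot(inherits(frame, "body_frame"))
  vec_in <- is.null(dim(points))
  if (vec_in) points <- matrix(points, nrow = 1L)
  out <- sweep(points %*% t(body_frame_rotation(frame)), 2L, -frame$origin)
  if (vec_in) out[1L, ] else out
}
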