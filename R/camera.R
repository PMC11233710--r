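#' Pinhole camera model with lens distortion
#'
#' Constructs a calibrated camera: pinhole intrinsics plus three radial and
#' two tangential distortion coefficients (OpenCV ordering k1, k2, p1, p2,
#' k3, with the radial terms supplied as `radial = c(k1, k2, k3)`).  The
#' extrinsic pose maps global coordinates (mm) to camera coordinates,
#' `X_cam = R %*% X + t`.
#'
#' @param focal length-2 numeric, focal lengths in pixels (fx, fy); both > 0.
#' @param principal_point length-2 numeric, principal point in pixels.
#' @param radial length-3 numeric, radial distortion coefficients (k1, k2, k3).
#' @param tangential length-2 numeric, tangential coefficients (p1, p2).
#' @param rotation 3x3 orthonormal matrix with determinant +1 (global to
#'   camera).
#' @param translation length-3 numeric, mm.
#' @param image_size length-2 numeric, image width and height in pixels.
#' @return an object of class `camera_model`.
#' @export
camera_model <- function(focal, principal_point,
                         radial = c(0, 0, 0), tangential = c(0, 0),
                         rotation = diag(3), translation = c(0, 0, 0),
                         image_size = c(896, 540)) {
  stopifnot(length(focal) == 2L, length(principal_point) == 2L,
            length(radial) == 3L, length(tangential) == 2L,
            length(translation) == 3L, length(image_size) == 2L)
  if (any(focal <= 0)) stop("focal lengths must be positive")
  rotation <- as.matrix(rotation)
  dimnames(rotation) <- NULL
  if (!is_rotation(rotation)) {
    stop("rotation must be orthonormal with determinant +1 (tol 1e-9)")
  }
  structure(list(focal = as.numeric(focal),
                 principal_point = as.numeric(principal_point),
                 radial = as.numeric(radial),
                 tangential = as.numeric(tangential),
                 rotation = rotation,
                 translation = as.numeric(translation),
                 image_size = as.numeric(image_size)),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat("<camera_model> focal", paste(signif(x$focal, 6), collapse = "/"),
      "px, pp", paste(signif(x$principal_point, 6), collapse = "/"),
      "px, image", paste(x$image_size, collapse = "x"), "px\n")
  invisible(x)
}

# distortion in normalized image coordinates
distort_normalized <- function(xy, cam) {
  x <- xy[, 1L]; y <- xy[, 2L]
  k <- cam$radial; p <- cam$tangential
  r2 <- x * x + y * y
  rad <- 1 + k[1L] * r2 + k[2L] * r2^2 + k[3L] * r2^3
  xd <- x * rad + 2 * p[1L] * x * y + p[2L] * (r2 + 2 * x * x)
  yd <- y * rad + p[1L] * (r2 + 2 * y * y) + 2 * p[2L] * x * y
  cbind(xd, yd)
}

#' Project 3D points into a camera
#'
#' Standard pinhole projection; when `apply_distortion` is `TRUE` the radial
#' and tangential distortion is applied in normalized coordinates before the
#' intrinsics.
#'
#' @param points3 length-3 vector or n x 3 matrix of global 3D positions (mm).
#' @param cam a [camera_model()].
#' @param apply_distortion logical; apply the lens-distortion model.
#' @return n x 2 matrix (or length-2 vector) of pixel coordinates.
#' @export
project <- function(points3, cam, apply_distortion = TRUE) {
  stopifnot(inherits(cam, "camera_model"))
  vec_in <- is.null(dim(points3))
  if (vec_in) points3 <- matrix(points3, nrow = 1L)
  pc <- points3 %*% t(cam$rotation) +
    matrix(cam$translation, nrow(points3), 3L, byrow = TRUE)
  if (any(pc[, 3L] <= 0)) {
    stop("point behind camera: non-positive depth after extrinsic transform")
  }
  xy <- pc[, 1:2, drop = FALSE] / pc[, 3L]
  if (apply_distortion) xy <- distort_normalized(xy, cam)
  px <- cbind(cam$focal[1L] * xy[, 1L] + cam$principal_point[1L],
              cam$focal[2L] * xy[, 2L] + cam$principal_point[2L])
  colnames(px) <- c("x_px", "y_px")
  if (vec_in) px[1L, ] else px
}

#' Correct pixel coordinates for lens distortion
#'
#' Inverts the distortion model by fixed-point iteration in normalized
#' coordinates (at most `max_iter` iterations, tolerance `tol`), returning
#' ideal (distortion-free) pixel coordinates such that re-applying the
#' distortion reproduces the input pixel.
#'
#' @param pixel length-2 vector or n x 2 matrix of observed pixels.
#' @param cam a [camera_model()].
#' @param max_iter,tol iteration controls (normalized coordinates).
#' @return undistorted pixel coordinates, same shape as input.
#' @export
undistort <- function(pixel, cam, max_iter = 50L, tol = 1e-10) {
  stopifnot(inherits(cam, "camera_model"))
  if (any(!is.finite(c(cam$radial, cam$tangential)))) {
    stop("distortion coefficients must be finite")
  }
  vec_in <- is.null(dim(pixel))
  if (vec_in) pixel <- matrix(pixel, nrow = 1L)
  xd <- cbind((pixel[, 1L] - cam$principal_point[1L]) / cam$focal[1L],
              (pixel[, 2L] - cam$principal_point[2L]) / cam$focal[2L])
  xy <- xd
  k <- cam$radial; p <- cam$tangential
  for (it in seq_len(max_iter)) {
    x <- xy[, 1L]; y <- xy[, 2L]
    r2 <- x * x + y * y
    rad <- 1 + k[1L] * r2 + k[2L] * r2^2 + k[3L] * r2^3
    dx <- 2 * p[1L] * x * y + p[2L] * (r2 + 2 * x * x)
    dy <- p[1L] * (r2 + 2 * y * y) + 2 * p[2L] * x * y
    xy_new <- cbind((xd[, 1L] - dx) / rad, (xd[, 2L] - dy) / rad)
    delta <- max(abs(xy_new - xy))
    xy <- xy_new
    if (delta < tol) break
  }
  resid <- max(abs(distort_normalized(xy, cam) - xd))
  if (resid > 1e-6) {
    stop("undistort did not converge: residual ", format(resid),
         " in normalized coordinates after ", max_iter, " iterations")
  }
  out <- cbind(cam$focal[1L] * xy[, 1L] + cam$principal_point[1L],
               cam$focal[2L] * xy[, 2L] + cam$principal_point[2L])
  colnames(out) <- c("x_px", "y_px")
  if (vec_in) out[1L, ] else out
}

#' A single 2D keypoint observation
#'
#' @param camera_id index (or name) of the observing camera.
#' @param pixel length-2 pixel coordinates.
#' @param valid logical validity flag.
#' @return an object of class `observation2d`.
#' @export
observation2d <- function(camera_id, pixel, valid = TRUE) {
  structure(list(camera_id = camera_id, pixel = as.numeric(pixel),
                 valid = isTRUE(valid)),
            class = "observation2d")
}

#' Triangulate a 3D point from multi-view 2D observations
#'
#' Observations are undistorted internally, then the homogeneous direct
#' linear transform (DLT) system is solved by singular value decomposition;
#' the right-singular vector of the smallest singular value gives the point.
#'
#' @param obs list of [observation2d()] (at least two valid, from distinct
#'   cameras).
#' @param cams list of [camera_model()] indexed by `camera_id`.
#' @return list with `point` (length-3, mm) and `reprojection_error_px`
#'   (mean distance between the input pixels and the reprojected point).
#' @export
triangulate <- function(obs, cams) {
  if (inherits(obs, "observation2d")) obs <- list(obs)
  keep <- vapply(obs, function(o) isTRUE(o$valid), logical(1L))
  obs <- obs[keep]
  ids <- vapply(obs, function(o) as.character(o$camera_id), character(1L))
  if (length(unique(ids)) < 2L) {
    stop("triangulation needs at least 2 valid observations from distinct cameras")
  }
  rows <- vector("list", 2L * length(obs))
  for (i in seq_along(obs)) {
    cam <- cams[[obs[[i]]$camera_id]]
    px <- cam$image_size
    if (any(obs[[i]]$pixel < 0) || any(obs[[i]]$pixel > px)) {
      warning("observation outside image bounds for camera ", ids[i])
    }
    ideal <- undistort(obs[[i]]$pixel, cam)
    K <- matrix(c(cam$focal[1L], 0, 0,
                  0, cam$focal[2L], 0,
                  cam$principal_point[1L], cam$principal_point[2L], 1), 3L, 3L)
    P <- K %*% cbind(cam$rotation, cam$translation)
    rows[[2L * i - 1L]] <- ideal[1L] * P[3L, ] - P[1L, ]
    rows[[2L * i]] <- ideal[2L] * P[3L, ] - P[2L, ]
  }
  A <- do.call(rbind, rows)
  sv <- svd(A)
  if (sv$d[3L] < 1e-12 * sv$d[1L]) {
    stop("degenerate triangulation geometry: DLT system is rank-deficient")
  }
  X <- sv$v[, 4L]
  if (abs(X[4L]) < 1e-14) {
    stop("degenerate triangulation geometry: point at infinity")
  }
  point <- X[1:3] / X[4L]
  errs <- vapply(obs, function(o) {
    vnorm(project(point, cams[[o$camera_id]], apply_distortion = TRUE) - o$pixel)
  }, numeric(1L))
  list(point = point, reprojection_error_px = mean(errs))
}

#' Read / write camera parameter files
#'
#' Cameras are stored as a JSON array with one record per camera holding the
#' `camera_model` fields (`rotation` row-major).
#'
#' @param path file path.
#' @param cams list of [camera_model()].
#' @return `read_cameras` returns a named list of `camera_model`s.
#' @export
read_cameras <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(raw, function(r) {
    camera_model(focal = unlist(r$focal),
                 principal_point = unlist(r$principal_point),
                 radial = unlist(r$radial),
                 tangential = unlist(r$tangential),
                 rotation = matrix(unlist(r$rotation), 3L, 3L, byrow = TRUE),
                 translation = unlist(r$translation),
                 image_size = unlist(r$image_size))
  })
  names(out) <- vapply(raw, function(r) as.character(r$id), character(1L))
  out
}

#' @rdname read_cameras
#' @export
write_cameras <- function(cams, path) {
  ids <- names(cams)
  if (is.null(ids)) ids <- as.character(seq_along(cams))
  recs <- lapply(seq_along(cams), function(i) {
    cam <- cams[[i]]
    list(id = ids[i], focal = cam$focal,
         principal_point = cam$principal_point,
         radial = cam$radial, tangential = cam$tangential,
         rotation = as.vector(t(cam$rotation)),
         translation = cam$translation, image_size = cam$image_size)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
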