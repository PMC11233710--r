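# Derived joint-kinematics quantities: model error and its AUC, angle
# post-processing and left/right mirroring, range of motion, femur-tibia
# plane rotation, and the DOF-ablation experiment.

#' Per-frame model error
#'
#' Summed Euclidean distance (micrometres) between the model's and the
#' tracked CxTr, TrFe, FeTi, TiTar and Tar positions.  Positions in body
#' coordinates are converted to global metric coordinates first when a
#' body frame is supplied (the conversion is rigid, so distances are
#' unchanged; it is offered so errors can be reported alongside global
#' data).
#'
#' @param fit_positions,tracked_positions 5 x 3 matrices or
#'   frames x 5 x 3 arrays (mm), same coordinate system.
#' @param frame optional [compute_body_frame()] used to convert both inputs
#'   to global coordinates before summing.
#' @return numeric vector of per-frame errors (um); frames with missing
#'   keypoints yield `NA` and carry the attribute `excluded`.
#' @export
model_error <- function(fit_positions, tracked_positions, frame = NULL) {
  as3d <- function(x) {
    if (length(dim(x)) == 2L) array(x, c(1L, dim(x))) else x
  }
  a <- as3d(fit_positions); b <- as3d(tracked_positions)
  stopifnot(all(dim(a) == dim(b)), dim(a)[2L] == 5L)
  if (!is.null(frame)) {
    for (f in seq_len(dim(a)[1L])) {
      a[f, , ] <- to_global(matrix(a[f, , ], 5L, 3L), frame)
      b[f, , ] <- to_global(matrix(b[f, , ], 5L, 3L), frame)
    }
  }
  err <- vapply(seq_len(dim(a)[1L]), function(f) {
    d <- sqrt(rowSums((matrix(a[f, , ], 5L, 3L) - matrix(b[f, , ], 5L, 3L))^2))
    sum(d) * 1000
  }, numeric(1L))
  excluded <- which(is.na(err))
  if (length(excluded)) attr(err, "excluded") <- excluded
  err
}

#' Integrate a phase-normalized series by Simpson's rule
#'
#' Composite Simpson integration of a uniformly sampled series on the
#' normalized phase interval [0, 1].  With 100 samples there are 99
#' (odd-count) intervals; the composite rule covers the first 96 and the
#' final three intervals are handled by Simpson's 3/8 rule, so the
#' quadrature remains exact for cubics.
#'
#' @param values numeric vector (>= 4 samples, no missing values) sampled
#'   uniformly on [0, 1].
#' @return the approximated integral (same units as `values` per unit
#'   normalized time).
#' @export
auc_simpson <- function(values) {
  y <- as.numeric(values)
  if (anyNA(y)) stop("series contains missing values")
  n <- length(y)
  if (n < 4L) stop("need at least 4 samples")
  h <- 1 / (n - 1L)
  n_int <- n - 1L
  if (n_int %% 2L == 0L) {
    return(simpson_even(y, h))
  }
  # odd interval count: Simpson over the first n_int - 3 intervals + 3/8 tail
  head_n <- n - 3L
  s <- simpson_even(y[seq_len(head_n)], h)
  tail_y <- y[(n - 3L):n]
  s + 3 * h / 8 * (tail_y[1L] + 3 * tail_y[2L] + 3 * tail_y[3L] + tail_y[4L])
}

simpson_even <- function(y, h) {
  n <- length(y)
  stopifnot((n - 1L) %% 2L == 0L)
  w <- rep(c(4, 2), length.out = n - 2L)
  h / 3 * (y[1L] + y[n] + sum(w * y[2:(n - 1L)]))
}

#' Post-process solver angles for reporting
#'
#' Converts solver-convention angles (0 degrees = straightened reference
#' posture) into the reporting convention: for left legs the signs of yaw
#' and roll angles are inverted (pitch untouched) so contralateral legs can
#' be combined, and 180 degrees is added to the CxTr-yaw and FeTi-yaw
#' angles so that 0 describes a fully flexed and 180 a fully extended
#' posture of the two main leg joints.
#'
#' @param angles data.frame or matrix of angles in degrees with DOF names
#'   (`"ThCx-yaw"`, ...) as column names.
#' @param leg leg identifier the angles belong to.
#' @return the post-processed angles, same shape.
#' @export
postprocess_angles <- function(angles, leg) {
  side <- side_of_leg(leg)
  out <- as.matrix(angles)
  nm <- colnames(out)
  if (is.null(nm)) stop("angle columns must be named by DOF")
  skel <- dof_table_skeleton()
  unknown <- setdiff(nm, skel$dof)
  if (length(unknown)) stop("unknown DOF name(s): ", paste(unknown, collapse = ", "))
  if (side == "left") {
    kinds <- skel$kind[match(nm, skel$dof)]
    flip <- kinds %in% c("yaw", "roll")
    out[, flip] <- -out[, flip]
  }
  for (dof in intersect(c("CxTr-yaw", "FeTi-yaw"), nm)) {
    out[, dof] <- out[, dof] + 180
  }
  out
}

#' Invert the left/right mirroring of angle signs
#'
#' Applies only the sign-inversion part of the left-leg convention (an
#' involution: applying it twice is the identity).
#'
#' @inheritParams postprocess_angles
#' @return angles with yaw and roll signs inverted.
#' @export
mirror_angle_signs <- function(angles) {
  out <- as.matrix(angles)
  skel <- dof_table_skeleton()
  kinds <- skel$kind[match(colnames(out), skel$dof)]
  if (anyNA(kinds)) stop("unknown DOF name(s) in angle columns")
  flip <- kinds %in% c("yaw", "roll")
  out[, flip] <- -out[, flip]
  out
}

#' Range of motion of joint DOF angles
#'
#' The ROM of a DOF is the difference between its maximum and minimum
#' observed angle.  With a grouping (e.g., fly identity), ROMs are
#' computed per group and summarized as mean and SD across groups.
#'
#' @param angles matrix/data.frame of angles in degrees (frames x DOFs,
#'   named columns).
#' @param grouping optional factor of length `nrow(angles)` (e.g., fly id).
#' @return object of class `rom_summary`: data.frame `per_group` (group,
#'   dof, min, max, range) and data.frame `pooled` (dof, mean_range,
#'   sd_range, n_groups).
#' @export
rom <- function(angles, grouping = NULL) {
  mat <- as.matrix(angles)
  if (nrow(mat) < 1L) stop("need at least one frame of angles")
  if (is.null(grouping)) grouping <- rep("all", nrow(mat))
  if (length(grouping) != nrow(mat)) stop("grouping length mismatch")
  grouping <- factor(grouping)
  if (nlevels(grouping) == 0L) stop("empty grouping")
  per <- do.call(rbind, lapply(levels(grouping), function(g) {
    sub <- mat[grouping == g, , drop = FALSE]
    data.frame(group = g, dof = colnames(mat),
               min = apply(sub, 2L, min, na.rm = TRUE),
               max = apply(sub, 2L, max, na.rm = TRUE), row.names = NULL)
  }))
  per$range <- per$max - per$min
  pooled <- do.call(rbind, lapply(unique(per$dof), function(d) {
    r <- per$range[per$dof == d]
    data.frame(dof = d, mean_range = mean(r),
               sd_range = if (length(r) > 1L) stats::sd(r) else 0,
               n_groups = length(r))
  }))
  structure(list(per_group = per, pooled = pooled), class = "rom_summary")
}

#' @export
print.rom_summary <- function(x, ...) {
  cat("<rom_summary>", nrow(x$pooled), "DOFs,",
      x$pooled$n_groups[1L], "group(s)\n")
  print(x$pooled, row.names = FALSE)
  invisible(x)
}

# unit plane normals (femur x tibia) with sign continuity across frames
ft_plane_normals <- function(TrFe, FeTi, TiTar) {
  n_frames <- nrow(TrFe)
  normals <- matrix(NA_real_, n_frames, 3L)
  for (f in seq_len(n_frames)) {
    femur <- FeTi[f, ] - TrFe[f, ]
    tibia <- TiTar[f, ] - FeTi[f, ]
    cr <- cross3(femur, tibia)
    if (vnorm(cr) < 1e-9 * vnorm(femur) * vnorm(tibia)) {
      stop("degenerate posture in frame ", f, ": femur and tibia collinear")
    }
    n <- normalize(cr)
    if (f > 1L && sum(n * normals[f - 1L, ]) < 0) n <- -n
    normals[f, ] <- n
  }
  normals
}

#' Rotation range of the femur-tibia plane
#'
#' The plane normal is the cross product of the femur vector (TrFe to
#' FeTi) and the tibia vector (FeTi to TiTar).  The rotation range over a
#' step-phase interval is the angle between the normals of the first and
#' the last posture (normal signs are kept continuous across frames to
#' avoid spurious 180-degree jumps).
#'
#' @param TrFe,FeTi,TiTar frames x 3 matrices of keypoint positions (mm).
#' @param interval integer range of frames to analyze (default: all).
#' @return rotation range in degrees.
#' @export
femur_tibia_plane_rotation <- function(TrFe, FeTi, TiTar,
                                       interval = seq_len(nrow(TrFe))) {
  TrFe <- as.matrix(TrFe)[interval, , drop = FALSE]
  FeTi <- as.matrix(FeTi)[interval, , drop = FALSE]
  TiTar <- as.matrix(TiTar)[interval, , drop = FALSE]
  if (nrow(TrFe) < 1L) stop("empty interval")
  normals <- ft_plane_normals(TrFe, FeTi, TiTar)
  d <- sum(normals[1L, ] * normals[nrow(normals), ])
  rad2deg(acos(pmin(pmax(d, -1), 1)))
}

#' DOF-ablation experiment on the femur-tibia plane rotation
#'
#' Re-poses a fitted sequence with only a subset of DOFs updated: the
#' first frame of the interval uses all fitted angles, every following
#' frame updates only the angles of `active_dofs` while the remaining
#' DOFs stay frozen at their first-frame values.  The femur-tibia
#' plane-rotation range of the resulting forward-kinematic postures is
#' compared to the full-model range.
#'
#' @param chain a `kinematic_chain`.
#' @param angles matrix of fitted angles in degrees (frames x DOFs, named
#'   columns covering the mobile DOFs).
#' @param active_dofs character vector of DOF names updated after frame 1
#'   (may be empty for a fully frozen posture).
#' @param interval integer range of frames (default: all).
#' @param tarsus_lengths optional per-frame tarsus lengths (mm).
#' @return list with `range_deg`, `full_range_deg` and `difference_deg`
#'   (subset minus full).
#' @export
dof_ablation <- function(chain, angles, active_dofs,
                         interval = seq_len(nrow(angles)),
                         tarsus_lengths = NULL) {
  stopifnot(inherits(chain, "kinematic_chain"))
  mat <- as.matrix(angles)[interval, , drop = FALSE]
  nm <- colnames(mat)
  mobile_names <- chain$dofs$dof[chain$dofs$mobile]
  if (!all(nm %in% chain$dofs$dof)) {
    stop("unknown DOF columns: ", paste(setdiff(nm, chain$dofs$dof), collapse = ", "))
  }
  bad <- setdiff(active_dofs, mobile_names)
  if (length(bad)) stop("active subset names immobile DOFs: ",
                        paste(bad, collapse = ", "))
  if (is.null(tarsus_lengths)) {
    tarsus_lengths <- rep(chain$tarsus_length, length(interval))
  } else {
    tarsus_lengths <- tarsus_lengths[interval]
  }
  pose_kp <- function(ang_named, L) {
    forward_kinematics(chain, stats::setNames(as.numeric(ang_named), nm),
                       tarsus_length = L)
  }
  n <- nrow(mat)
  kp_full <- array(NA_real_, c(n, 5L, 3L))
  kp_sub <- array(NA_real_, c(n, 5L, 3L))
  frozen <- mat[1L, ]
  for (f in seq_len(n)) {
    kp_full[f, , ] <- pose_kp(mat[f, ], tarsus_lengths[f])
    sub <- frozen
    sub[nm %in% active_dofs] <- mat[f, nm %in% active_dofs]
    kp_sub[f, , ] <- pose_kp(sub, tarsus_lengths[f])
  }
  rng <- function(kp) femur_tibia_plane_rotation(kp[, 2L, ], kp[, 3L, ], kp[, 4L, ])
  full_range <- rng(kp_full)
  sub_range <- rng(kp_sub)
  list(range_deg = sub_range, full_range_deg = full_range,
       difference_deg = sub_range - full_range)
}
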