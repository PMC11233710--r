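# Kinematic leg chains built from condyle landmarks.
#
# A chain is an ordered list of 14 rotational DOFs (yaw/pitch/roll for ThCx,
# CxTr, TrFe, FeTi; yaw/pitch for TiTar).  The yaw axis of each joint is the
# unit vector between its condyles, the roll axis runs along the leg segment
# the joint controls, and the pitch axis is their cross product.  All
# positions are expressed in body coordinates (ThAp at the origin, x
# anterior, y left, z dorsal).

SEGMENTS <- c("coxa", "trochanter", "femur", "tibia", "tarsus")

dh_transform <- function(theta, alpha, d, r) {
  ct <- cos(theta); st <- sin(theta)
  ca <- cos(alpha); sa <- sin(alpha)
  matrix(c(ct, st, 0, 0,
           -st * ca, ct * ca, sa, 0,
           st * sa, -ct * sa, ca, 0,
           r * ct, r * st, d, 1), 4L, 4L)
}

# chain scale used for tolerance decisions
chain_scale <- function(chain) sum(chain$seg_lengths)

#' Build a kinematic chain for one leg
#'
#' Derives the per-DOF rotational axes from the condyle landmarks (yaw:
#' normalized condyle_b - condyle_a; roll: direction of the controlled
#' segment, i.e., joint center to next joint center or to the tarsus tip for
#' TiTar; pitch: yaw cross roll), assembles the Denavit-Hartenberg local
#' frames and parameters, and stores the reference posture.  All landmark
#' positions are converted to body coordinates first.
#'
#' @param landmarks a [condyle_landmarks()] set.
#' @param leg leg identifier (`R1`, `L1`, ...).
#' @param dof_config named list of mobile DOFs per joint (see
#'   [default_dof_config()]).
#' @param model `"oblique"` or `"orthogonalized"`; selects the default angle
#'   bound table.
#' @param bounds optional data.frame overriding [dof_bounds()] (columns
#'   `dof`, `lo_deg`, `hi_deg`).
#' @param anteroposterior hint axis for the body frame construction.
#' @return an object of class `kinematic_chain`.
#' @export
build_chain <- function(landmarks, leg, dof_config = default_dof_config(leg),
                        model = c("oblique", "orthogonalized"), bounds = NULL,
                        anteroposterior = c(1, 0, 0)) {
  stopifnot(inherits(landmarks, "condyle_landmarks"))
  model <- match.arg(model)
  if (is.null(landmarks$legs[[leg]])) stop("missing landmarks for leg ", leg)
  frame <- compute_body_frame(landmarks$body$ThAp, landmarks$body$lWH,
                              landmarks$body$rWH, anteroposterior)
  lm_body <- leg_landmarks_to_body(landmarks$legs[[leg]], frame)
  chain_from_body_landmarks(lm_body, leg, dof_config, model, bounds,
                            body_rWH = to_body(landmarks$body$rWH, frame),
                            body_lWH = to_body(landmarks$body$lWH, frame))
}

# convert one leg's landmark list into body coordinates
leg_landmarks_to_body <- function(leg_lm, frame) {
  out <- leg_lm
  for (joint in names(leg_lm$joints)) {
    out$joints[[joint]] <- lapply(leg_lm$joints[[joint]],
                                  function(p) to_body(as.numeric(p), frame))
  }
  out$tarsus_tip <- to_body(as.numeric(leg_lm$tarsus_tip), frame)
  out
}

# core constructor from body-coordinate landmarks
chain_from_body_landmarks <- function(lm, leg, dof_config, model, bounds,
                                      straightened = FALSE,
                                      body_rWH = NULL, body_lWH = NULL) {
  skel <- dof_table_skeleton()
  mob <- mobility_vector(dof_config)
  btab <- dof_bounds(leg, model)
  if (!is.null(bounds)) {
    idx <- match(bounds$dof, btab$dof)
    if (anyNA(idx)) stop("unknown DOF in bounds override: ",
                         paste(bounds$dof[is.na(idx)], collapse = ", "))
    btab$lo_deg[idx] <- bounds$lo_deg
    btab$hi_deg[idx] <- bounds$hi_deg
  }
  if (any(btab$lo_deg >= btab$hi_deg)) stop("angle bounds must satisfy min < max")

  centers5 <- t(vapply(lm$joints[JOINTS], function(j) as.numeric(j$center),
                       numeric(3L)))
  rownames(centers5) <- JOINTS
  tip <- as.numeric(lm$tarsus_tip)
  pts6 <- rbind(centers5, Tar = tip)
  seg_lengths <- vnorm_rows(diff(pts6))
  names(seg_lengths) <- SEGMENTS
  if (any(seg_lengths <= 0)) stop("segment lengths must be positive")

  # per-joint axes
  axes <- matrix(NA_real_, 14L, 3L)
  centers <- matrix(NA_real_, 14L, 3L)
  for (j in seq_along(JOINTS)) {
    joint <- JOINTS[j]
    jl <- lm$joints[[joint]]
    yaw <- normalize(as.numeric(jl$condyle_b) - as.numeric(jl$condyle_a),
                     paste0(joint, " condyle axis"))
    seg_vec <- pts6[j + 1L, ] - pts6[j, ]
    roll <- normalize(seg_vec, paste0(joint, " segment"))
    cr <- cross3(yaw, roll)
    if (vnorm(cr) < 1e-6) {
      stop("joint ", joint, ": yaw axis nearly parallel to the leg segment, ",
           "pitch axis undefined")
    }
    pitch <- normalize(cr)
    rows <- which(skel$joint == joint)
    for (r in rows) {
      axes[r, ] <- switch(skel$kind[r], yaw = yaw, pitch = pitch, roll = roll)
      centers[r, ] <- centers5[joint, ]
    }
  }

  chain <- structure(list(
    leg = leg, side = side_of_leg(leg), model = model,
    landmarks_body = lm,
    dofs = cbind(skel, mobile = mob, btab[, c("lo_deg", "hi_deg")]),
    dof_config = dof_config,
    axes = axes, centers = centers,
    seg_lengths = seg_lengths,
    keypoints_ref = pts6[KEYPOINTS, ],
    thcx_ref = centers5["ThCx", ],
    body_rWH = body_rWH, body_lWH = body_lWH,
    tarsus_length = unname(seg_lengths["tarsus"]),
    straightened = straightened
  ), class = "kinematic_chain")
  build_dh(chain)
}

vnorm_rows <- function(m) sqrt(rowSums(m * m))

#' @export
print.kinematic_chain <- function(x, ...) {
  cat("<kinematic_chain>", x$leg, paste0("(", x$model, " model)"),
      sum(x$dofs$mobile), "mobile of 14 DOFs\n")
  cat("  segment lengths (mm):",
      paste(sprintf("%s=%.3f", names(x$seg_lengths), x$seg_lengths),
            collapse = ", "), "\n")
  invisible(x)
}

#' Construct Denavit-Hartenberg frames and parameters for a chain
#'
#' Each DOF's local coordinate system (LCS) has its z axis along the DOF's
#' rotational axis.  The x axis and origin follow the classical cases: (a)
#' skew axes use the common normal, with the origin at its foot on the
#' DOF's own axis; (b) intersecting axes use the normal of the plane the
#' two axes span, with the origin at the intersection; (c) parallel axes
#' use the common normal passing through the DOF's joint center, which also
#' serves as the origin.  The first LCS takes its x axis from the cross
#' product of its z axis with the body x axis and sits at the ThCx; the
#' end-effector frame reuses the last TiTar axis with its origin at the
#' tarsus tip.  The joint angle theta and twist alpha are signed angles
#' between consecutive x and z axes; the offsets d and r come from the feet
#' of the common normal between consecutive z axes.  The composed
#' transforms are verified to reproduce every LCS before the chain is
#' returned.
#'
#' @param chain a `kinematic_chain` (normally called internally by
#'   [build_chain()]).
#' @return the chain with `frames`, `dh`, `B` and keypoint attachment data
#'   filled in.
#' @export
build_dh <- function(chain) {
  stopifnot(inherits(chain, "kinematic_chain"))
  scale <- chain_scale(chain)
  n <- 14L
  tip <- chain$keypoints_ref["Tar", ]
  frames <- vector("list", n + 1L)

  # first frame: ThCx-yaw
  Z <- chain$axes[1L, ]
  Xcr <- cross3(Z, c(1, 0, 0))          # body x axis
  if (vnorm(Xcr) < 1e-9) {
    stop("ThCx yaw axis parallel to the body x axis; first LCS undefined")
  }
  X <- normalize(Xcr)
  frames[[1L]] <- list(origin = chain$centers[1L, ], X = X,
                       Y = cross3(Z, X), Z = Z)

  for (i in 2L:(n + 1L)) {
    if (i <= n) {
      Zi <- chain$axes[i, ]; ci <- chain$centers[i, ]
    } else {
      Zi <- chain$axes[n, ]; ci <- tip   # end effector duplicates last TiTar axis
    }
    prev <- frames[[i - 1L]]
    cl <- line_line_closest(prev$origin, prev$Z, ci, Zi, par_tol = 1e-9)
    if (cl$parallel) {
      off <- ci - prev$origin
      perp <- off - sum(off * prev$Z) * prev$Z
      if (vnorm(perp) < 1e-12 * max(scale, 1)) {
        Xi <- prev$X                      # coincident axes: keep previous x
      } else {
        Xi <- normalize(perp)
      }
      origin <- ci
    } else if (cl$gap < 1e-9 * scale) {  # intersecting
      Xi <- normalize(cross3(prev$Z, Zi))
      origin <- (cl$q1 + cl$q2) / 2
    } else {                             # skew: common normal
      Xi <- normalize(cl$q2 - cl$q1)
      origin <- cl$q2
    }
    frames[[i]] <- list(origin = origin, X = Xi, Y = cross3(Zi, Xi), Z = Zi)
  }

  dh <- matrix(NA_real_, n, 4L, dimnames = list(NULL, c("theta0", "alpha", "d", "r")))
  for (i in seq_len(n)) {
    Fi <- frames[[i]]; Fn <- frames[[i + 1L]]
    off <- Fn$origin - Fi$origin
    dh[i, "theta0"] <- signed_angle(Fi$X, Fn$X, Fi$Z)
    dh[i, "alpha"] <- signed_angle(Fi$Z, Fn$Z, Fn$X)
    dh[i, "d"] <- sum(off * Fi$Z)
    dh[i, "r"] <- sum(off * Fn$X)
    # D-H validity: the origin offset must decompose into d*Z_i + r*X_{i+1}
    resid <- vnorm(off - dh[i, "d"] * Fi$Z - dh[i, "r"] * Fn$X)
    if (resid > 1e-8 * max(scale, 1)) {
      stop("D-H construction failed between DOFs ", i, " and ", i + 1L,
           ": origin offset not in the Z/X plane (residual ", format(resid), " mm)")
    }
  }

  B <- homog(cbind(frames[[1L]]$X, frames[[1L]]$Y, frames[[1L]]$Z),
             frames[[1L]]$origin)
  chain$frames <- frames
  chain$dh <- dh
  chain$B <- B

  # verify that composing the transforms reproduces every LCS
  pose <- B
  for (i in seq_len(n)) {
    pose <- pose %*% dh_transform(dh[i, "theta0"], dh[i, "alpha"],
                                  dh[i, "d"], dh[i, "r"])
    Fn <- frames[[i + 1L]]
    err <- max(abs(pose - homog(cbind(Fn$X, Fn$Y, Fn$Z), Fn$origin)))
    if (err > 1e-9 * max(scale, 1)) {
      stop("D-H self-consistency check failed at frame ", i + 1L,
           " (max deviation ", format(err), ")")
    }
  }

  # keypoint attachment: local coordinates in the pose of the first DOF of
  # the joint distal to the keypoint's proximal link
  kp_frame <- c(CxTr = 4L, TrFe = 7L, FeTi = 10L, TiTar = 13L, Tar = 15L)
  poses <- fk_poses(chain, numeric(n))
  kp_local <- matrix(NA_real_, 5L, 3L, dimnames = list(KEYPOINTS, NULL))
  for (k in seq_along(KEYPOINTS)) {
    inv <- invert_homog(poses[[kp_frame[k]]])
    kp_local[k, ] <- apply_homog(inv, chain$keypoints_ref[k, ])
  }
  inv15 <- invert_homog(poses[[15L]])
  titar_local <- apply_homog(inv15, chain$keypoints_ref["TiTar", ])
  u_global <- normalize(tip - chain$keypoints_ref["TiTar", ], "tarsus direction")
  u_local <- as.vector(t(poses[[15L]][1:3, 1:3]) %*% u_global)
  chain$kp_frame <- kp_frame
  chain$kp_local <- kp_local
  chain$tar_local <- list(titar = titar_local, u = u_local)
  chain
}

# poses (4x4) of every frame for a full 14-vector of DOF angles (radians)
fk_poses <- function(chain, ang14) {
  dh <- chain$dh
  pose <- chain$B
  poses <- vector("list", 15L)
  poses[[1L]] <- pose
  for (i in 1:14) {
    pose <- pose %*% dh_transform(dh[i, "theta0"] + ang14[i], dh[i, "alpha"],
                                  dh[i, "d"], dh[i, "r"])
    poses[[i + 1L]] <- pose
  }
  poses
}

# fast keypoint positions (mm, body coordinates) for full angles in radians
fk_keypoints_rad <- function(chain, ang14, tarsus_length = chain$tarsus_length) {
  dh <- chain$dh
  pose <- chain$B
  need <- chain$kp_frame
  out <- matrix(NA_real_, 5L, 3L, dimnames = list(KEYPOINTS, c("x", "y", "z")))
  kidx <- 1L
  for (i in 1:14) {
    pose <- pose %*% dh_transform(dh[i, "theta0"] + ang14[i], dh[i, "alpha"],
                                  dh[i, "d"], dh[i, "r"])
    while (kidx <= 4L && need[kidx] == i + 1L) {
      out[kidx, ] <- apply_homog(pose, chain$kp_local[kidx, ])
      kidx <- kidx + 1L
    }
  }
  out["Tar", ] <- apply_homog(pose, chain$tar_local$titar +
                                tarsus_length * chain$tar_local$u)
  out
}

# expand a user angle vector (degrees; named for mobile DOFs or full 14)
expand_angles <- function(chain, angles) {
  if (length(angles) == 14L && is.null(names(angles))) {
    ang <- as.numeric(angles)
  } else {
    ang <- numeric(14L)
    idx <- match(names(angles), chain$dofs$dof)
    if (anyNA(idx)) stop("unknown DOF name(s): ",
                         paste(names(angles)[is.na(idx)], collapse = ", "))
    ang[idx] <- as.numeric(angles)
  }
  if (any(abs(ang) > 360)) stop("joint angles outside +/-360 degrees")
  deg2rad(ang)
}

#' Forward kinematics of a leg chain
#'
#' Computes the positions of the CxTr, TrFe, FeTi, TiTar keypoints and the
#' tarsus tip (body coordinates, mm) for a set of joint angles.  Angles are
#' in degrees, either a full 14-vector in chain order or a named vector for
#' a subset of DOFs (remaining DOFs are held at their reference value 0).
#'
#' @param chain a [build_chain()] result.
#' @param angles joint angles in degrees (see above).
#' @param tarsus_length optional tarsus length (mm) for this evaluation;
#'   defaults to the chain's current value.
#' @return 5 x 3 matrix of keypoint positions with rownames
#'   `CxTr, TrFe, FeTi, TiTar, Tar`.
#' @export
forward_kinematics <- function(chain, angles = numeric(14L),
                               tarsus_length = chain$tarsus_length) {
  stopifnot(inherits(chain, "kinematic_chain"))
  fk_keypoints_rad(chain, expand_angles(chain, angles), tarsus_length)
}

#' Straighten the initial posture of a chain
#'
#' Adjusts the yaw DOF angle of every joint distal to the ThCx so that
#' consecutive leg segments become collinear (the inner segment angle is
#' maximized about the yaw axis, in closed form), applies the corresponding
#' rotations to the distal landmarks, and rebuilds the chain so that the
#' all-zero angle set denotes the extended posture.  Pitch and roll DOFs
#' are left untouched to preserve the anatomical relation between segments
#' and rotational axes.
#'
#' @param chain a [build_chain()] result built from the raw (e.g., uCT)
#'   posture.
#' @return the straightened chain, with attribute `yaw_adjustments_deg`
#'   (named, degrees) recording the applied rotations.
#' @export
straighten_initial_posture <- function(chain) {
  stopifnot(inherits(chain, "kinematic_chain"))
  lm <- chain$landmarks_body
  adj <- c(CxTr = 0, TrFe = 0, FeTi = 0, TiTar = 0)
  for (j in 2:5) {                      # joints CxTr..TiTar
    joint <- JOINTS[j]
    pts6 <- rbind(t(vapply(lm$joints[JOINTS], function(x) as.numeric(x$center),
                           numeric(3L))), as.numeric(lm$tarsus_tip))
    ctr <- pts6[j, ]
    u <- ctr - pts6[j - 1L, ]
    v <- pts6[j + 1L, ] - ctr
    jl <- lm$joints[[joint]]
    ax <- normalize(as.numeric(jl$condyle_b) - as.numeric(jl$condyle_a))
    v_par <- sum(v * ax) * ax
    v_perp <- v - v_par
    a_cos <- sum(u * v_perp)
    a_sin <- sum(u * cross3(ax, v_perp))
    if (sqrt(a_cos^2 + a_sin^2) < 1e-12 * vnorm(u) * vnorm(v)) {
      if (vnorm(cross3(u, v)) < 1e-9 * vnorm(u) * vnorm(v) && sum(u * v) > 0) {
        next                            # already collinear
      }
      stop("joint ", joint, ": yaw rotation cannot extend the segments ",
           "(axis parallel to both segments)")
    }
    phi <- atan2(a_sin, a_cos)
    adj[joint] <- rad2deg(phi)
    # rotate everything distal to this joint about the yaw axis through it
    if (j < 5L) {
      for (jj in (j + 1L):5L) {
        lm$joints[[JOINTS[jj]]] <- lapply(lm$joints[[JOINTS[jj]]], function(p) {
          rotate_about_axis(as.numeric(p), ax, phi, ctr)
        })
      }
    }
    lm$tarsus_tip <- rotate_about_axis(as.numeric(lm$tarsus_tip), ax, phi, ctr)
  }
  out <- chain_from_body_landmarks(lm, chain$leg, chain$dof_config,
                                   chain$model, NULL, straightened = TRUE,
                                   body_rWH = chain$body_rWH,
                                   body_lWH = chain$body_lWH)
  out$dofs[, c("lo_deg", "hi_deg")] <- chain$dofs[, c("lo_deg", "hi_deg")]
  attr(out, "yaw_adjustments_deg") <- adj
  out
}

#' Scale a chain to an individual fly
#'
#' A similarity transform (rotation, translation, uniform scale) mapping the
#' model's reference triangle (this leg's ThCx, rWH, lWH) onto the fly's is
#' applied to the condyle landmarks; each segment except the tarsus is then
#' rescaled to the median motion-captured length by translating the distal
#' landmarks along the segment, preserving all axis directions.
#'
#' @param chain a straightened [build_chain()] result.
#' @param fly_ThCx,fly_rWH,fly_lWH length-3 positions of the fly's reference
#'   triangle, in the fly's body coordinates (mm).
#' @param median_segment_lengths named numeric, median tracked lengths (mm)
#'   for `coxa`, `trochanter`, `femur`, `tibia` (a `tarsus` entry, if
#'   present, is ignored -- the tarsus is adjusted per frame instead).
#' @return the rescaled chain.
#' @export
scale_to_fly <- function(chain, fly_ThCx, fly_rWH, fly_lWH,
                         median_segment_lengths = NULL) {
  stopifnot(inherits(chain, "kinematic_chain"))
  if (is.null(chain$body_rWH) || is.null(chain$body_lWH)) {
    stop("chain lacks body wing-hinge reference positions; rebuild with build_chain()")
  }
  model_tri <- rbind(chain$thcx_ref, chain$body_rWH, chain$body_lWH)
  fly_tri <- rbind(as.numeric(fly_ThCx), as.numeric(fly_rWH), as.numeric(fly_lWH))
  if (vnorm(cross3(fly_tri[2L, ] - fly_tri[1L, ],
                   fly_tri[3L, ] - fly_tri[1L, ])) < 1e-9) {
    stop("degenerate fly reference triangle")
  }
  mc <- colMeans(model_tri); fc <- colMeans(fly_tri)
  A <- sweep(model_tri, 2L, mc); Bm <- sweep(fly_tri, 2L, fc)
  s <- sqrt(sum(Bm^2) / sum(A^2))
  sv <- svd(crossprod(A, Bm))           # Kabsch rotation model -> fly
  D <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% D %*% t(sv$u)
  trans <- function(p) as.vector(fc + s * (R %*% (as.numeric(p) - mc)))

  lm <- chain$landmarks_body
  for (joint in names(lm$joints)) lm$joints[[joint]] <- lapply(lm$joints[[joint]], trans)
  lm$tarsus_tip <- trans(lm$tarsus_tip)

  if (!is.null(median_segment_lengths)) {
    if (any(median_segment_lengths <= 0)) stop("median segment lengths must be positive")
    for (j in 1:4) {                    # coxa..tibia; tarsus handled per frame
      seg <- SEGMENTS[j]
      if (!seg %in% names(median_segment_lengths)) next
      target <- as.numeric(median_segment_lengths[[seg]])
      from <- as.numeric(lm$joints[[JOINTS[j]]]$center)
      to <- as.numeric(lm$joints[[JOINTS[j + 1L]]]$center)
      dir <- normalize(to - from, paste0(seg, " segment"))
      shift <- (target - vnorm(to - from)) * dir
      for (jj in (j + 1L):5) {
        lm$joints[[JOINTS[jj]]] <- lapply(lm$joints[[JOINTS[jj]]],
                                          function(p) as.numeric(p) + shift)
      }
      lm$tarsus_tip <- as.numeric(lm$tarsus_tip) + shift
    }
  }
  out <- chain_from_body_landmarks(lm, chain$leg, chain$dof_config,
                                   chain$model, NULL,
                                   straightened = chain$straightened,
                                   body_rWH = trans(chain$body_rWH),
                                   body_lWH = trans(chain$body_lWH))
  out$dofs[, c("lo_deg", "hi_deg")] <- chain$dofs[, c("lo_deg", "hi_deg")]
  out
}

#' Set the (freely adjustable) tarsus length of a chain
#'
#' Only the TiTar-to-tip segment length changes; under forward kinematics
#' the tip moves along the tarsus direction.  Used per frame to absorb the
#' apparent length changes caused by tarsus bending.
#'
#' @param chain a `kinematic_chain`.
#' @param length tarsus length in mm (> 0).
#' @return the chain with the new tarsus length.
#' @export
set_tarsus_length <- function(chain, length) {
  stopifnot(inherits(chain, "kinematic_chain"))
  if (!is.finite(length) || length <= 0) stop("tarsus length must be positive")
  chain$tarsus_length <- length
  chain$seg_lengths["tarsus"] <- length
  chain
}

#' Orthogonalized model variant of a chain
#'
#' Replaces every yaw axis by the (signed) body coordinate axis with the
#' largest absolute cosine to the original axis, writes new condyle
#' positions at the joint center plus/minus that axis, and linearizes the
#' leg: all segments point straight down (negative body z) from the ThCx
#' with their original lengths.  Pitch and roll axes are re-derived from the
#' new geometry and the orthogonalized-model angle bounds are installed.
#' Exact ties in the axis cosine are broken preferring body y, then z, then
#' x.
#'
#' @param chain a straightened `kinematic_chain` with condyle-based axes.
#' @return the orthogonalized chain.
#' @export
orthogonalize <- function(chain) {
  stopifnot(inherits(chain, "kinematic_chain"))
  lm <- chain$landmarks_body
  basis <- list(y = c(0, 1, 0), z = c(0, 0, 1), x = c(1, 0, 0))  # tie-break order
  down <- c(0, 0, -1)
  ctr <- as.numeric(lm$joints$ThCx$center)
  for (j in seq_along(JOINTS)) {
    joint <- JOINTS[j]
    jl <- lm$joints[[joint]]
    ax <- normalize(as.numeric(jl$condyle_b) - as.numeric(jl$condyle_a))
    best <- NULL; best_dot <- -Inf
    for (nm in names(basis)) {
      dt <- sum(ax * basis[[nm]])
      if (abs(dt) > best_dot + 1e-15) {  # strict improvement keeps tie order
        best_dot <- abs(dt)
        best <- if (dt < 0) -basis[[nm]] else basis[[nm]]
      }
    }
    sep <- vnorm(as.numeric(jl$condyle_b) - as.numeric(jl$condyle_a)) / 2
    lm$joints[[joint]] <- list(condyle_a = ctr - sep * best,
                               condyle_b = ctr + sep * best,
                               center = ctr)
    seg_len <- chain$seg_lengths[SEGMENTS[j]]
    ctr <- ctr + seg_len * down          # next joint center (or tip)
  }
  lm$tarsus_tip <- ctr
  chain_from_body_landmarks(lm, chain$leg, chain$dof_config,
                            "orthogonalized", NULL,
                            straightened = chain$straightened,
                            body_rWH = chain$body_rWH,
                            body_lWH = chain$body_lWH)
}
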