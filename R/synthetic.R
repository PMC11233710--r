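# Synthetic fly: landmark sets, walking simulation, camera rigs and noisy
# 2D observations with full ground truth, sized to match the real setup
# (leg span ~2 mm, 3 mm treadmill-ball radius, 400 Hz, ~5.9 um/px).

# fixed per-joint axis-obliquity pattern (multiples of the obliquity angle):
# first entry tilts the condyle axis about the segment (roll) direction,
# second tilts it towards the segment
.obliquity_pattern <- list(
  ThCx  = c(1.0, 0.5),
  CxTr  = c(-1.0, 0.3),
  TrFe  = c(0.6, -0.8),
  FeTi  = c(-0.4, 1.0),
  TiTar = c(0.8, -0.5))

.syn_segments <- list(
  front  = c(coxa = 0.30, trochanter = 0.10, femur = 0.50, tibia = 0.40, tarsus = 0.45),
  middle = c(coxa = 0.25, trochanter = 0.10, femur = 0.55, tibia = 0.45, tarsus = 0.55),
  hind   = c(coxa = 0.28, trochanter = 0.10, femur = 0.60, tibia = 0.55, tarsus = 0.60))

.syn_thcx <- list(
  front  = c(0.55, -0.18, -0.30),
  middle = c(0.30, -0.22, -0.32),
  hind   = c(0.05, -0.20, -0.31))

# condyle labeling sign per pair and joint: +1 keeps the default order,
# -1 swaps the condyles so that the positive yaw direction admitted by the
# angle constraints flexes the segment towards the treadmill ball (the
# hind femur-tibia joint flexes anteriorly in the animal)
.syn_axis_sign <- list(
  front  = c(ThCx = 1, CxTr = 1, TrFe = 1, FeTi = 1, TiTar = 1),
  middle = c(ThCx = 1, CxTr = 1, TrFe = 1, FeTi = 1, TiTar = 1),
  hind   = c(ThCx = 1, CxTr = 1, TrFe = 1, FeTi = -1, TiTar = 1))

#' Generate a six-legged synthetic condyle landmark set
#'
#' Produces a bilaterally symmetric fly in a canonical frame (ThAp at the
#' origin, x anterior, y left, z dorsal; wing hinges anterior and slightly
#' ventral of the ThAp).  Legs hang straight down from their ThCx so the
#' zero-angle posture is already extended.  Each joint's condyle (yaw) axis
#' starts from the body y axis and is tilted by `obliquity` degrees in a
#' fixed per-joint pattern; at `obliquity = 0` all yaw axes coincide with
#' body axes and the landmark set equals its own orthogonalized variant.
#' The seed only drives a small (+/-2 %) per-leg-pair jitter of the segment
#' lengths, applied before mirroring so bilateral symmetry is exact.
#'
#' @param seed integer seed.
#' @param scale overall scale factor (1 = adult fly, leg span about 2 mm).
#' @param obliquity condyle-axis obliquity in degrees (0 = axes aligned with
#'   body axes, i.e., orthogonal model geometry).
#' @param length_jitter relative jitter amplitude of segment lengths.
#' @return a [condyle_landmarks()] set with legs R1, L1, R2, L2, R3, L3.
#' @export
make_synthetic_fly <- function(seed = 1L, scale = 1, obliquity = 15,
                               length_jitter = 0.02) {
  if (scale <= 0) stop("scale must be positive")
  set.seed(seed)
  body <- list(ThAp = c(0, 0, 0) * scale,
               lWH = c(0.45, 0.28, -0.12) * scale,
               rWH = c(0.45, -0.28, -0.12) * scale)
  down <- c(0, 0, -1)
  sep <- 0.06 * scale                    # condyle separation
  legs <- list()
  for (p in seq_along(names(.syn_segments))) {
    pair <- names(.syn_segments)[p]
    segs <- .syn_segments[[pair]] * scale
    segs <- segs * (1 + length_jitter * stats::runif(5L, -1, 1))
    ctr <- .syn_thcx[[pair]] * scale
    joints <- list()
    for (j in seq_along(JOINTS)) {
      joint <- JOINTS[j]
      pat <- .obliquity_pattern[[joint]]
      ax <- c(0, 1, 0)
      if (obliquity != 0) {
        ax <- rotate_about_axis(ax, down, deg2rad(obliquity * pat[1L]))
        tilt_axis <- cross3(ax, down)    # tilt towards the segment direction
        ax <- rotate_about_axis(ax, tilt_axis, deg2rad(obliquity * pat[2L]))
      }
      ax <- normalize(ax) * .syn_axis_sign[[pair]][joint]
      joints[[joint]] <- list(condyle_a = ctr - (sep / 2) * ax,
                              condyle_b = ctr + (sep / 2) * ax,
                              center = ctr)
      ctr <- ctr + segs[j] * down
    }
    legs[[paste0("R", p)]] <- list(joints = joints, tarsus_tip = ctr)
  }
  lms <- condyle_landmarks(legs, body)
  for (p in 1:3) {
    lms$legs[[paste0("L", p)]] <- mirror_leg_landmarks(lms, paste0("R", p))
  }
  condyle_landmarks(lms$legs[c("R1", "L1", "R2", "L2", "R3", "L3")], body)
}

#' Synthetic six-camera rig around the fly
#'
#' Cameras look at `target` from azimuths spread around the body, slightly
#' below the horizontal plane, at the stated working distance.  Defaults
#' emulate the experimental resolution of about 5.9 um per pixel.
#'
#' @param n_cameras number of cameras (>= 2).
#' @param distance working distance in mm.
#' @param focal_px focal length in pixels.
#' @param image_size image width/height in pixels.
#' @param target look-at point (mm).
#' @param radial,tangential distortion coefficients shared by all cameras.
#' @return named list of [camera_model()]s.
#' @export
make_camera_rig <- function(n_cameras = 6L, distance = 50, focal_px = 8500,
                            image_size = c(896, 540), target = c(0.2, 0, -1.5),
                            radial = c(-0.08, 0.02, 0.001),
                            tangential = c(1e-4, -1e-4)) {
  if (n_cameras < 2L) stop("a rig needs at least 2 cameras")
  az <- seq(0, 2 * pi, length.out = n_cameras + 1L)[seq_len(n_cameras)] + 0.3
  elev <- deg2rad(-10)
  cams <- list()
  for (i in seq_len(n_cameras)) {
    pos <- target + distance * c(cos(az[i]) * cos(elev),
                                 sin(az[i]) * cos(elev), -sin(elev))
    z_cam <- normalize(target - pos)
    up <- c(0, 0, 1)
    x_cam <- normalize(cross3(z_cam, up))
    y_cam <- cross3(z_cam, x_cam)
    R <- rbind(x_cam, y_cam, z_cam)
    cams[[sprintf("cam%d", i)]] <- camera_model(
      focal = c(focal_px, focal_px), principal_point = image_size / 2,
      radial = radial, tangential = tangential,
      rotation = R, translation = as.vector(-R %*% pos),
      image_size = image_size)
  }
  cams
}

# solve the tarsus length that puts the tip at distance `target_dist` from
# `center`, moving along direction u from the TiTar position; of the
# admissible line-sphere intersections, take the one closest to the
# nominal length
.solve_tarsus_length <- function(titar, u, center, target_dist, nominal,
                                 range = c(0.05, 2)) {
  a <- titar - center
  au <- sum(a * u)
  disc <- au * au - sum(a * a) + target_dist^2
  if (disc < 0 && disc > -1e-9 * target_dist^2) disc <- 0
  if (disc < 0) {
    stop("ball geometry unreachable: tarsus line misses the target sphere")
  }
  eps <- 1e-6 * diff(range)
  roots <- c(-au - sqrt(disc), -au + sqrt(disc))
  roots <- roots[roots >= range[1L] - eps & roots <= range[2L] + eps]
  if (length(roots) == 0L) {
    stop("implausible tarsus length while pinning the tip (no root in [",
         paste(signif(range, 3), collapse = ", "), "] mm)")
  }
  min(max(roots[which.min(abs(roots - nominal))], range[1L]), range[2L])
}

# distance from `center` reachable by the tip along direction u from the
# TiTar, for tarsus lengths within `range`: returns c(min, max)
.reachable_band <- function(titar, u, center, range) {
  a <- titar - center
  f <- function(L) sqrt(sum((a + L * u)^2))
  Lstar <- min(max(-sum(a * u), range[1L]), range[2L])
  c(f(Lstar), max(f(range[1L]), f(range[2L])))
}

# base stance posture per leg pair (right-leg convention, degrees): front
# legs splayed forward, hind legs backward, all pairs abducted so that the
# six tarsus tips land near a common 3 mm sphere under the body
.gait_base_posture <- list(
  "ThCx-yaw" = c(front = -30, middle = 0, hind = 35),
  "ThCx-pitch" = c(front = 10, middle = 20, hind = 10),
  "TiTar-yaw" = c(front = 25, middle = 0, hind = 0),
  "TiTar-pitch" = c(front = 0, middle = -20, hind = 0))

# smooth periodic angle waveforms for the mobile DOFs of one chain, phase-
# locked to the leg's own step cycle (`cyc` in [0,1), stance first): every
# DOF reaches its extremes at the touchdown/lift-off transitions, so the
# leg sweeps between its anterior and posterior extreme during stance and
# returns during swing.  Amplitudes follow right-leg conventions; on left
# legs yaw/roll amplitudes and base offsets are sign-inverted (mirror
# gait).  All waveforms are verified against the chain's angle bounds.
.gait_waveforms <- function(chain, cyc) {
  amp_map <- c("ThCx-yaw" = -8, "ThCx-pitch" = 6, "ThCx-roll" = 4,
               "CxTr-yaw" = 10, "CxTr-pitch" = 4, "CxTr-roll" = 4,
               "TrFe-yaw" = 5, "TrFe-pitch" = 4, "TrFe-roll" = 6,
               "FeTi-yaw" = 14, "FeTi-pitch" = 4, "FeTi-roll" = 5,
               "TiTar-yaw" = 6, "TiTar-pitch" = 5)
  ph_map <- c("ThCx-yaw" = 0, "ThCx-pitch" = 0.3, "ThCx-roll" = -0.3,
              "CxTr-yaw" = 0.4, "CxTr-pitch" = -0.2, "CxTr-roll" = 0.2,
              "TrFe-yaw" = 0.3, "TrFe-pitch" = -0.3, "TrFe-roll" = 0.25,
              "FeTi-yaw" = -0.25, "FeTi-pitch" = 0.2, "FeTi-roll" = -0.2,
              "TiTar-yaw" = 0.2, "TiTar-pitch" = -0.2)
  pair <- leg_pair(chain$leg)
  ang <- matrix(0, length(cyc), 14L)
  colnames(ang) <- chain$dofs$dof
  for (i in which(chain$dofs$mobile)) {
    dof <- chain$dofs$dof[i]
    lo <- chain$dofs$lo_deg[i]; hi <- chain$dofs$hi_deg[i]
    amp <- unname(amp_map[dof])
    base <- 0
    if (!is.null(.gait_base_posture[[dof]])) {
      base <- unname(.gait_base_posture[[dof]][pair])
    }
    if (chain$side == "left" && chain$dofs$kind[i] %in% c("yaw", "roll")) {
      base <- -base
      amp <- -amp
    }
    # keep the waveform inside the bounds, as close to the base stance
    # posture as they allow, with a 2 deg safety margin
    offset <- min(max(base, lo + abs(amp) + 2), hi - abs(amp) - 2)
    w <- offset + amp * cos(2 * pi * cyc + ph_map[dof])
    if (any(w < lo) || any(w > hi)) {
      stop("generated waveform for ", dof, " violates its angle bounds")
    }
    ang[, i] <- w
  }
  ang
}

#' Simulate walking on a spherical treadmill with ground truth
#'
#' Drives the mobile DOFs of one or more leg chains with smooth periodic
#' waveforms (flexion/extension, promotion/remotion) at the given cadence,
#' and modulates the tarsus length per frame so that the tarsus tip lies
#' exactly on the treadmill ball during stance and at a controlled
#' clearance above it during swing (emulating tarsus bending).  Gaussian
#' noise of the stated standard deviation is added to all keypoints;
#' the noiseless keypoints, true angles, tarsus lengths, phase labels and
#' ball geometry are retained as ground truth.
#'
#' @param chains a single `kinematic_chain` or a named list of chains
#'   (one per simulated leg); legs in the canonical tripod groups
#'   (R1/L2/R3 vs L1/R2/L3) step in antiphase.
#' @param n_steps number of complete step cycles.
#' @param cadence step frequency in Hz.
#' @param seed integer seed for the noise draws.
#' @param noise_sigma_um keypoint noise standard deviation in micrometres.
#' @param fps video frame rate in Hz.
#' @param ball_radius treadmill ball radius in mm.
#' @param duty stance fraction of the cycle.
#' @param swing_gap minimum tip clearance above the ball during swing (mm).
#' @param swing_lift additional mid-swing lift amplitude (mm).
#' @return an object of class `synthetic_scenario`: per-leg true angles
#'   (`angles`, degrees, frames x 14), noiseless (`keypoints_true`) and noisy
#'   (`keypoints`) keypoint arrays (frames x 5 x 3), per-frame tarsus
#'   lengths, logical stance matrix `stance`, `ball` (center, radius), and
#'   the generating chains and parameters.
#' @export
simulate_walking <- function(chains, n_steps = 4L, cadence = 8, seed = 1L,
                             noise_sigma_um = 0, fps = 400,
                             ball_radius = 3, duty = 0.5,
                             swing_gap = 0.08, swing_lift = 0.25) {
  if (inherits(chains, "kinematic_chain")) {
    chains <- stats::setNames(list(chains), chains$leg)
  }
  period <- fps / cadence
  n_frames <- as.integer(round(n_steps * period))
  tt <- (seq_len(n_frames) - 1L) / period      # time in step cycles
  tripod2 <- c("L1", "R2", "L3")
  set.seed(seed)

  # cycle phase per leg: stance during the first `duty` of the cycle
  cyc <- lapply(names(chains), function(leg) {
    (tt + if (leg %in% tripod2) 0.5 else 0) %% 1
  })
  names(cyc) <- names(chains)

  angles <- lapply(names(chains), function(leg) {
    .gait_waveforms(chains[[leg]], cyc[[leg]])
  })
  names(angles) <- names(chains)
  stance <- vapply(names(chains), function(leg) cyc[[leg]] < duty,
                   logical(n_frames))

  # nominal FK (nominal tarsus length) to place the ball under the stance tips
  fk_nom <- lapply(names(chains), function(leg) {
    ch <- chains[[leg]]
    t(vapply(seq_len(n_frames), function(f) {
      fk_keypoints_rad(ch, deg2rad(angles[[leg]][f, ]))["Tar", ]
    }, numeric(3L)))
  })
  names(fk_nom) <- names(chains)
  stance_tips <- do.call(rbind, lapply(names(chains),
                                       function(l) fk_nom[[l]][stance[, l], , drop = FALSE]))
  if (nrow(stance_tips) == 0L) stop("no stance frames generated")
  # place the ball under the stance-tip centroid on the body midline and
  # fit only its depth: a free 3D sphere fit drifts along the body axis
  # because the tip cloud does not follow the sphere curvature exactly;
  # the per-frame tarsus-length modulation absorbs the radial residuals
  cxy <- c(mean(stance_tips[, 1L]), 0)
  z_cost <- function(z) {
    cen <- c(cxy, z)
    sum((sqrt(rowSums(sweep(stance_tips, 2L, cen)^2)) - ball_radius)^2)
  }
  z0 <- mean(stance_tips[, 3L]) - ball_radius
  zopt <- stats::optimize(z_cost, c(z0 - 1, z0 + 1))$minimum
  ball_center <- c(cxy, zopt)
  # the tibia-tarsus joint must stay far enough outside the ball that (a)
  # a positive tarsus length can pin the tip onto the surface in stance and
  # (b) the shortest admissible swing tarsus still clears radius + gap;
  # lower the ball until that holds
  titar_all <- do.call(rbind, lapply(names(chains), function(leg) {
    ch <- chains[[leg]]
    t(vapply(seq_len(n_frames), function(f) {
      fk_keypoints_rad(ch, deg2rad(angles[[leg]][f, ]))["TiTar", ]
    }, numeric(3L)))
  }))
  # with the tibia-tarsus joint at least radius + gap + 0.06 from the
  # center, a tarsus as short as 0.05 mm always reaches radius + gap + 0.01
  # regardless of its direction, so the swing clearance is guaranteed
  margin <- swing_gap + 0.06
  for (it in seq_len(40L)) {
    dmin <- min(sqrt(rowSums(sweep(titar_all, 2L, ball_center)^2)))
    if (dmin >= ball_radius + margin) break
    ball_center[3L] <- ball_center[3L] - (ball_radius + margin - dmin + 0.01)
  }

  kp_true <- list(); tarsus <- list()
  for (leg in names(chains)) {
    ch <- chains[[leg]]
    kt <- array(NA_real_, c(n_frames, 5L, 3L),
                dimnames = list(NULL, KEYPOINTS, c("x", "y", "z")))
    Ls <- numeric(n_frames)
    nominal <- unname(ch$seg_lengths["tarsus"])
    swing_range <- c(0.05, 2)
    for (f in seq_len(n_frames)) {
      ang <- deg2rad(angles[[leg]][f, ])
      base <- fk_keypoints_rad(ch, ang)   # tip row replaced after pinning
      titar <- base["TiTar", ]
      u <- normalize(base["Tar", ] - titar)
      if (stance[f, leg]) {
        target <- ball_radius
        rng <- c(0.05, 2)
      } else {
        # honor the prescribed clearance profile where the leg geometry
        # allows it; otherwise use the nearest reachable clearance, which
        # is always at least ball_radius + swing_gap
        tau <- (cyc[[leg]][f] - duty) / (1 - duty)
        desired <- ball_radius + swing_gap + swing_lift * sin(pi * tau)
        band <- .reachable_band(titar, u, ball_center, swing_range)
        if (band[2L] < ball_radius + swing_gap) {
          stop("leg ", leg, " cannot clear the ball during swing (frame ", f, ")")
        }
        target <- min(max(desired, band[1L]), band[2L])
        rng <- swing_range
      }
      Ls[f] <- .solve_tarsus_length(titar, u, ball_center, target,
                                    nominal = nominal, range = rng)
      kt[f, , ] <- fk_keypoints_rad(ch, ang, tarsus_length = Ls[f])
    }
    kp_true[[leg]] <- kt
    tarsus[[leg]] <- Ls
  }

  kp_noisy <- lapply(kp_true, function(kt) {
    if (noise_sigma_um > 0) {
      kt + array(stats::rnorm(length(kt), 0, noise_sigma_um / 1000), dim(kt))
    } else kt
  })

  structure(list(seed = seed, chains = chains, angles = angles,
                 keypoints_true = kp_true, keypoints = kp_noisy,
                 tarsus_lengths = tarsus, stance = stance,
                 ball = list(center = ball_center, radius = ball_radius),
                 fps = fps, cadence = cadence, duty = duty,
                 noise_sigma_um = noise_sigma_um,
                 swing_gap = swing_gap, swing_lift = swing_lift),
            class = "synthetic_scenario")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat("<synthetic_scenario>", length(x$chains), "legs,",
      nrow(x$angles[[1L]]), "frames at", x$fps, "Hz, cadence",
      x$cadence, "Hz, noise", x$noise_sigma_um, "um\n")
  invisible(x)
}

#' Render noisy 2D observations of 3D keypoints into a camera rig
#'
#' Projects every keypoint into every camera (lens distortion applied) and
#' adds Gaussian pixel noise.  No occlusion model: all observations are
#' marked valid.
#'
#' @param keypoints3d n x 3 matrix of 3D positions (mm).
#' @param rig list of [camera_model()]s (>= 2).
#' @param pixel_sigma pixel noise standard deviation.
#' @param seed integer seed for the noise draws.
#' @return data.frame with columns `point`, `camera_id`, `x_px`, `y_px`,
#'   `valid`.
#' @export
render_observations <- function(keypoints3d, rig, pixel_sigma = 0, seed = 1L) {
  if (length(rig) < 2L) stop("a rig needs at least 2 cameras")
  keypoints3d <- as.matrix(keypoints3d)
  set.seed(seed)
  ids <- names(rig)
  if (is.null(ids)) ids <- as.character(seq_along(rig))
  out <- do.call(rbind, lapply(seq_along(rig), function(ci) {
    px <- project(keypoints3d, rig[[ci]], apply_distortion = TRUE)
    if (pixel_sigma > 0) px <- px + matrix(stats::rnorm(length(px), 0, pixel_sigma),
                                           nrow(px), 2L)
    data.frame(point = seq_len(nrow(keypoints3d)), camera_id = ids[ci],
               x_px = px[, 1L], y_px = px[, 2L], valid = TRUE)
  }))
  rownames(out) <- NULL
  out
}
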