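test_that("chain axes follow the condyle construction", {
  ch <- fixture_chain("R2", straightened = FALSE)
  fly <- fixture_fly()
  for (joint in c("ThCx", "CxTr", "TrFe", "FeTi", "TiTar")) {
    rows <- which(ch$dofs$joint == joint)
    yaw <- ch$axes[rows[ch$dofs$kind[rows] == "yaw"], ]
    roll_row <- rows[ch$dofs$kind[rows] == "roll"]
    pitch <- ch$axes[rows[ch$dofs$kind[rows] == "pitch"], ]
    # pitch orthogonal to yaw and roll (roll axis = segment direction)
    expect_lt(abs(sum(pitch * yaw)), 1e-12)
    if (length(roll_row)) {
      expect_lt(abs(sum(pitch * ch$axes[roll_row, ])), 1e-12)
    }
    # all axes unit
    for (r in rows) expect_equal(sqrt(sum(ch$axes[r, ]^2)), 1, tolerance = 1e-12)
  }
})

test_that("zero angles reproduce the stored reference posture", {
  for (leg in c("R1", "L2", "R3")) {
    ch <- fixture_chain(leg)
    expect_lt(max(abs(forward_kinematics(ch) - ch$keypoints_ref)), 1e-9)
  }
})

test_that("forward kinematics preserves segment lengths for any angles", {
  ch <- fixture_chain("R1")
  set.seed(31)
  for (i in 1:25) {
    fk <- forward_kinematics(ch, runif(14, -40, 40))
    lens <- sqrt(rowSums(diff(fk)^2))
    expect_equal(unname(lens),
                 unname(ch$seg_lengths[c("trochanter", "femur", "tibia", "tarsus")]),
                 tolerance = 1e-9)
    # coxa: ThCx (fixed chain base) to CxTr
    expect_equal(sqrt(sum((fk["CxTr", ] - ch$thcx_ref)^2)),
                 unname(ch$seg_lengths["coxa"]), tolerance = 1e-9)
  }
  expect_error(forward_kinematics(ch, c(400, numeric(13))), "360")
})

test_that("D-H forward kinematics equals the sequential Rodrigues oracle", {
  set.seed(32)
  for (i in 1:30) {
    leg <- sample(c("R1", "L1", "R2", "L2", "R3", "L3"), 1L)
    ch <- fixture_chain(leg, obliquity = sample(c(0, 10, 15, 25), 1L))
    ang <- runif(14, -35, 35)
    expect_lt(max(abs(forward_kinematics(ch, ang) - oracle_fk(ch, ang))), 1e-8)
  }
})

test_that("a single FeTi yaw rotation rigidly rotates the distal leg", {
  ch <- fixture_chain("R2")
  row <- which(ch$dofs$dof == "FeTi-yaw")
  phi <- 27.5
  ang <- setNames(numeric(14L), ch$dofs$dof)
  ang[row] <- phi
  fk <- forward_kinematics(ch, ang)
  ref <- ch$keypoints_ref
  expected <- rodrigues_rotate(ref[c("TiTar", "Tar"), ], ch$axes[row, ],
                               phi * pi / 180, ch$centers[row, ])
  expect_lt(max(abs(fk[c("TiTar", "Tar"), ] - expected)), 1e-9)
  # proximal keypoints untouched
  expect_lt(max(abs(fk[c("CxTr", "TrFe", "FeTi"), ] -
                      ref[c("CxTr", "TrFe", "FeTi"), ])), 1e-9)
})

test_that("D-H cases produce the expected parameters", {
  ch <- fixture_chain("R2", straightened = FALSE)
  # within a joint, yaw and pitch axes intersect orthogonally at the joint
  # center: d = r = 0 and twist +/-90 degrees (case b)
  for (joint in c("ThCx", "CxTr", "TrFe", "FeTi", "TiTar")) {
    i <- which(ch$dofs$dof == paste0(joint, "-yaw"))
    expect_lt(abs(ch$dh[i, "d"]), 1e-9)
    expect_lt(abs(ch$dh[i, "r"]), 1e-9)
    expect_equal(unname(abs(ch$dh[i, "alpha"])), pi / 2, tolerance = 1e-9)
  }
  # end-effector frame duplicates the last TiTar axis at the tarsus tip:
  # parallel axes (case c), twist zero, offsets matching the tip position
  expect_lt(abs(ch$dh[14L, "alpha"]), 1e-12)
  f14 <- ch$frames[[14L]]; f15 <- ch$frames[[15L]]
  expect_equal(f15$Z, f14$Z, tolerance = 1e-12)
  expect_equal(f15$origin, unname(ch$keypoints_ref["Tar", ]), tolerance = 1e-12)
  off <- f15$origin - f14$origin
  expect_equal(unname(ch$dh[14L, "d"]), sum(off * f14$Z), tolerance = 1e-12)
  expect_equal(unname(ch$dh[14L, "r"]),
               sqrt(sum(off^2) - sum(off * f14$Z)^2), tolerance = 1e-9)
})

test_that("every local frame is orthonormal and right-handed", {
  for (leg in c("R1", "L3")) {
    ch <- fixture_chain(leg)
    for (f in ch$frames) {
      R <- cbind(f$X, f$Y, f$Z)
      expect_lt(max(abs(crossprod(R) - diag(3L))), 1e-9)
      expect_gt(det(R), 1 - 1e-9)
    }
    expect_lt(max(abs(crossprod(ch$B[1:3, 1:3]) - diag(3L))), 1e-9)
  }
})

test_that("straightening recovers a constructed single bend", {
  fly <- fixture_fly(obliquity = 12)
  ch0 <- straighten_initial_posture(build_chain(fly, "R2"))
  # bend the leg 30 degrees about the FeTi yaw axis, then rebuild from the
  # bent landmarks: straightening must undo exactly that rotation
  lm <- ch0$landmarks_body
  row <- which(ch0$dofs$dof == "FeTi-yaw")
  ax <- ch0$axes[row, ]; ctr <- ch0$centers[row, ]
  bend <- function(p) rodrigues_rotate(as.numeric(p), ax, 30 * pi / 180, ctr)
  lm$joints$TiTar <- lapply(lm$joints$TiTar, bend)
  lm$tarsus_tip <- bend(lm$tarsus_tip)
  bent <- condylefit:::chain_from_body_landmarks(lm, "R2",
                                                 default_dof_config("R2"),
                                                 "oblique", NULL)
  restraight <- straighten_initial_posture(bent)
  adj <- attr(restraight, "yaw_adjustments_deg")
  expect_equal(unname(adj["FeTi"]), -30, tolerance = 1e-9)
  expect_lt(max(abs(restraight$keypoints_ref - ch0$keypoints_ref)), 1e-9)
  # already-straight chain: identity
  again <- straighten_initial_posture(ch0)
  expect_lt(max(abs(attr(again, "yaw_adjustments_deg"))), 1e-9)
})

test_that("after straightening, zero angles give collinear segments", {
  ch <- fixture_chain("R3")
  fk <- forward_kinematics(ch)
  pts <- rbind(ch$thcx_ref, fk)
  dirs <- diff(pts)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  for (i in 2:nrow(dirs)) {
    expect_equal(unname(dirs[i, ]), unname(dirs[1L, ]), tolerance = 1e-9)
  }
})

test_that("left-leg FK is the sagittal mirror of the right leg", {
  set.seed(33)
  for (p in 1:3) {
    chR <- fixture_chain(paste0("R", p))
    chL <- fixture_chain(paste0("L", p))
    A <- runif(14, -30, 30)
    Ainv <- A
    flip <- chR$dofs$kind %in% c("yaw", "roll")
    Ainv[flip] <- -A[flip]
    fkR <- forward_kinematics(chR, A)
    fkL <- forward_kinematics(chL, Ainv)
    fkL[, 2L] <- -fkL[, 2L]            # sagittal plane is y = 0 in body coords
    expect_lt(max(abs(fkR - fkL)), 1e-9)
  }
})

test_that("mirrored landmark sets satisfy the constructor invariants", {
  fly <- fixture_fly()
  mirrored <- mirror_leg_landmarks(fly, "R1")
  direct <- fly$legs$L1
  for (joint in names(direct$joints)) {
    expect_equal(mirrored$joints[[joint]]$center,
                 direct$joints[[joint]]$center, tolerance = 1e-12)
  }
  expect_equal(mirrored$tarsus_tip, direct$tarsus_tip, tolerance = 1e-12)
})

test_that("scale_to_fly identity and similarity cases", {
  ch <- fixture_chain("R2")
  # identity: fly triangle == model triangle, medians == model lengths
  med <- as.list(ch$seg_lengths[c("coxa", "trochanter", "femur", "tibia")])
  same <- scale_to_fly(ch, ch$thcx_ref, ch$body_rWH, ch$body_lWH, med)
  expect_lt(max(abs(same$keypoints_ref - ch$keypoints_ref)), 1e-9)
  # uniform 1.2x similarity: all lengths scale, axis directions unchanged
  s <- 1.2
  scaled <- scale_to_fly(ch, s * ch$thcx_ref, s * ch$body_rWH, s * ch$body_lWH)
  expect_equal(unname(scaled$seg_lengths), unname(s * ch$seg_lengths),
               tolerance = 1e-9)
  expect_lt(max(abs(scaled$axes - ch$axes)), 1e-9)
  # per-segment medians honored after scaling
  med2 <- list(coxa = 0.3, trochanter = 0.12, femur = 0.61, tibia = 0.5)
  resc <- scale_to_fly(ch, s * ch$thcx_ref, s * ch$body_rWH, s * ch$body_lWH, med2)
  expect_equal(unname(resc$seg_lengths[c("coxa", "trochanter", "femur", "tibia")]),
               unlist(med2, use.names = FALSE), tolerance = 1e-9)
  # axes remain unit and pitch orthogonal after scaling
  expect_equal(unname(sqrt(rowSums(resc$axes^2))), rep(1, 14L), tolerance = 1e-9)
  expect_error(scale_to_fly(ch, c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
               "degenerate")
})

test_that("tarsus length is freely adjustable and only moves the tip", {
  ch <- fixture_chain("R1")
  L0 <- ch$tarsus_length
  expect_equal(set_tarsus_length(ch, L0)$tarsus_length, L0)
  ang <- runif(14, -20, 20)
  fk1 <- forward_kinematics(ch, ang)
  fk2 <- forward_kinematics(set_tarsus_length(ch, 2 * L0), ang)
  expect_lt(max(abs(fk1[1:4, ] - fk2[1:4, ])), 1e-12)
  expect_equal(sqrt(sum((fk2["Tar", ] - fk2["TiTar", ])^2)), 2 * L0,
               tolerance = 1e-9)
  # tip moves along the tarsus direction
  u1 <- fk1["Tar", ] - fk1["TiTar", ]
  u2 <- fk2["Tar", ] - fk2["TiTar", ]
  expect_equal(u2 / sqrt(sum(u2^2)), u1 / sqrt(sum(u1^2)), tolerance = 1e-9)
  expect_error(set_tarsus_length(ch, -1), "positive")
})

test_that("orthogonalize snaps axes to body axes and conserves lengths", {
  ch <- fixture_chain("R2", obliquity = 10)
  orth <- orthogonalize(ch)
  expect_identical(orth$model, "orthogonalized")
  # every yaw axis is now a signed body axis with positive dot to original
  for (joint in c("ThCx", "CxTr", "TrFe", "FeTi", "TiTar")) {
    i <- which(ch$dofs$joint == joint & ch$dofs$kind == "yaw")
    ax <- orth$axes[i, ]
    expect_equal(sort(abs(ax)), c(0, 0, 1), tolerance = 1e-12)
    expect_gt(sum(ax * ch$axes[i, ]), 0)
  }
  expect_equal(unname(orth$seg_lengths), unname(ch$seg_lengths), tolerance = 1e-9)
  # segments point straight down from the ThCx
  fk <- forward_kinematics(orth)
  expect_lt(max(abs(sweep(fk[, 1:2], 2L, orth$thcx_ref[1:2]))), 1e-9)
})
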