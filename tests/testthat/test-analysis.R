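test_that("model error is the summed keypoint distance in micrometres", {
  a <- matrix(rnorm(15), 5L, 3L)
  expect_equal(model_error(a, a), 0)
  b <- a; b[3L, ] <- b[3L, ] + c(0.01, 0, 0)       # 10 um on one keypoint
  expect_equal(model_error(a, b), 10, tolerance = 1e-9)
  # displace every keypoint by a 1 um vector: summed error is 5 um
  b2 <- a + 1 / sqrt(3) / 1000
  expect_equal(model_error(a, b2), 5, tolerance = 1e-9)
  # rigid conversion to global coordinates leaves distances unchanged
  bf <- compute_body_frame(c(0.1, 0, 0), c(0.5, 0.3, -0.1), c(0.5, -0.3, -0.1))
  expect_equal(model_error(a, b, frame = bf), model_error(a, b),
               tolerance = 1e-9)
  # missing keypoint: frame excluded with flag
  arr_a <- array(a, c(1L, 5L, 3L)); arr_b <- array(b, c(1L, 5L, 3L))
  arr_b[1L, 2L, 1L] <- NA
  err <- model_error(arr_a, arr_b)
  expect_true(is.na(err[1L]))
  expect_identical(attr(err, "excluded"), 1L)
})

test_that("Simpson AUC is exact for low-order polynomials on the 100 grid", {
  tt <- seq(0, 1, length.out = 100L)
  expect_equal(auc_simpson(rep(3.7, 100L)), 3.7, tolerance = 1e-12)
  expect_equal(auc_simpson(tt), 0.5, tolerance = 1e-12)
  expect_equal(auc_simpson(tt^2), 1 / 3, tolerance = 1e-6)
  expect_equal(auc_simpson(tt^3), 1 / 4, tolerance = 1e-9)   # exact for cubics
  expect_error(auc_simpson(c(1, NA, 3, 4)), "missing")
  expect_error(auc_simpson(c(1, 2)), "at least 4")
})

test_that("Simpson AUC is linear", {
  set.seed(61)
  f <- rnorm(100L); g <- rnorm(100L)
  a <- 2.3; b <- -0.7
  expect_equal(auc_simpson(a * f + b * g),
               a * auc_simpson(f) + b * auc_simpson(g), tolerance = 1e-12)
})

test_that("angle post-processing follows the reporting conventions", {
  ang <- matrix(0, 2L, 4L,
                dimnames = list(NULL, c("FeTi-yaw", "CxTr-yaw", "ThCx-yaw",
                                        "ThCx-pitch")))
  ang[2L, ] <- c(10, -20, 10, 10)
  # right leg: only the two main yaws are shifted by 180
  outR <- postprocess_angles(ang, "R2")
  expect_equal(unname(outR[1L, ]), c(180, 180, 0, 0))
  expect_equal(unname(outR[2L, ]), c(190, 160, 10, 10))
  # left leg: yaw signs inverted first (pitch exempt), then the shift
  outL <- postprocess_angles(ang, "L2")
  expect_equal(unname(outL[2L, ]), c(170, 200, -10, 10))
  expect_error(postprocess_angles(matrix(0, 1, 1, dimnames = list(NULL, "Hip-yaw")),
                                  "R1"), "unknown DOF")
})

test_that("left-right sign mirroring is an involution", {
  set.seed(62)
  ang <- matrix(rnorm(42), 3L, 14L,
                dimnames = list(NULL, dof_bounds("R1")$dof))
  once <- mirror_angle_signs(ang)
  expect_false(isTRUE(all.equal(once, ang)))
  expect_equal(mirror_angle_signs(once), ang, tolerance = 1e-15)
})

test_that("range of motion summarizes per group and pooled", {
  frames <- 400L
  tt <- seq(0, 4 * pi, length.out = frames)
  A <- 17
  ang <- cbind("FeTi-yaw" = A * sin(tt), "ThCx-roll" = rep(2, frames))
  r <- rom(ang)
  expect_equal(r$pooled$mean_range[r$pooled$dof == "FeTi-yaw"], 2 * A,
               tolerance = 0.01)
  expect_equal(r$pooled$mean_range[r$pooled$dof == "ThCx-roll"], 0)
  # single frame: zero range
  r1 <- rom(ang[1L, , drop = FALSE])
  expect_true(all(r1$pooled$mean_range == 0))
  # grouping: per-fly ROMs averaged
  grp <- rep(c("fly1", "fly2"), each = frames / 2L)
  rg <- rom(ang, grp)
  expect_identical(rg$pooled$n_groups[1L], 2L)
  expect_error(rom(ang[0L, , drop = FALSE]), "at least one frame")
})

test_that("femur-tibia plane rotation recovers a constructed rigid rotation", {
  # static posture: zero rotation
  TrFe <- matrix(rep(c(0, 0, 0), 5L), 5L, 3L, byrow = TRUE)
  FeTi <- matrix(rep(c(0.5, 0, -0.1), 5L), 5L, 3L, byrow = TRUE)
  TiTar <- matrix(rep(c(0.7, 0.2, -0.5), 5L), 5L, 3L, byrow = TRUE)
  expect_equal(femur_tibia_plane_rotation(TrFe, FeTi, TiTar), 0, tolerance = 1e-9)
  # rigid rotation by 42.6 degrees about an axis lying in the femur-tibia
  # plane (perpendicular to the plane normal), so the normal itself turns
  # by exactly the rotation angle
  femur <- FeTi[1L, ] - TrFe[1L, ]
  tibia <- TiTar[1L, ] - FeTi[1L, ]
  axis <- femur + 0.4 * tibia
  n <- 40L
  angles <- seq(0, 42.6, length.out = n) * pi / 180
  rot <- function(p) t(vapply(angles, function(a) {
    rodrigues_rotate(p, axis, a, c(0.1, -0.2, 0.3))
  }, numeric(3L)))
  expect_equal(femur_tibia_plane_rotation(rot(TrFe[1L, ]), rot(FeTi[1L, ]),
                                          rot(TiTar[1L, ])),
               42.6, tolerance = 1e-6)
  # invariant to uniform scaling of the leg
  expect_equal(femur_tibia_plane_rotation(2 * rot(TrFe[1L, ]), 2 * rot(FeTi[1L, ]),
                                          2 * rot(TiTar[1L, ])),
               42.6, tolerance = 1e-6)
  # collinear femur and tibia: degenerate
  expect_error(femur_tibia_plane_rotation(matrix(0, 2, 3),
                                          matrix(c(1, 0, 0), 2, 3, byrow = TRUE),
                                          matrix(c(2, 0, 0), 2, 3, byrow = TRUE)),
               "collinear")
})

test_that("dof_ablation freezes and updates the requested DOF subsets", {
  sc <- fixture_scenario()
  leg <- "R2"
  ch <- sc$chains[[leg]]
  mob <- ch$dofs$dof[ch$dofs$mobile]
  ang <- sc$angles[[leg]][11:40, mob]
  Ls <- sc$tarsus_lengths[[leg]]
  full <- dof_ablation(ch, ang, active_dofs = mob, tarsus_lengths = Ls[11:40])
  expect_identical(full$difference_deg, 0)
  frozen <- dof_ablation(ch, ang, active_dofs = character(0L),
                         tarsus_lengths = Ls[11:40])
  # acos() of a unit dot product is accurate to ~sqrt(eps) near zero angle
  expect_lt(frozen$range_deg, 1e-5)
  expect_error(dof_ablation(ch, ang, active_dofs = "TrFe-roll"), "immobile")
})

test_that("a plane rotation generated by the two proximal yaws is recovered", {
  ch <- fixture_chain("R2")
  mob <- ch$dofs$dof[ch$dofs$mobile]
  n <- 30L
  ang <- matrix(0, n, length(mob), dimnames = list(NULL, mob))
  ang[, "FeTi-yaw"] <- 30          # constant bend so the plane is defined
  ang[, "ThCx-yaw"] <- seq(0, -25, length.out = n)
  ang[, "CxTr-yaw"] <- seq(0, -30, length.out = n)
  res <- dof_ablation(ch, ang, active_dofs = c("ThCx-yaw", "CxTr-yaw"))
  expect_gt(res$full_range_deg, 5)
  expect_lt(abs(res$difference_deg), 1e-6)
  # a strict subset leaves a clearly nonzero residual rotation
  partial <- dof_ablation(ch, ang, active_dofs = "ThCx-yaw")
  expect_gt(abs(partial$difference_deg), 0.3)
})
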