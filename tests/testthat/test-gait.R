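test_that("exact sphere data recovers the center to machine precision", {
  set.seed(51)
  cen <- c(0.3, -0.1, -4.8)
  # points on the upper cap of a 3 mm sphere
  theta <- runif(200, 0, 0.45 * pi)
  phi <- runif(200, 0, 2 * pi)
  pts <- cbind(cen[1L] + 3 * sin(theta) * cos(phi),
               cen[2L] + 3 * sin(theta) * sin(phi),
               cen[3L] + 3 * cos(theta))
  expect_lt(sqrt(sum((estimate_ball_center(pts, 3) - cen)^2)), 1e-6)
})

test_that("swing points outside the sphere do not bias the center", {
  # the asymmetric penalty makes the stance shell ~100x stiffer than the
  # one-sided pull of the swing points, so the swing cloud (here 1/5 of
  # the data, 0.1-0.4 mm off the ball) shifts the center by well under the
  # stance-noise scale
  set.seed(52)
  cen <- c(0, 0, -4)
  theta <- runif(300, 0, 0.4 * pi); phi <- runif(300, 0, 2 * pi)
  on_sphere <- cbind(cen[1L] + 3 * sin(theta) * cos(phi),
                     cen[2L] + 3 * sin(theta) * sin(phi),
                     cen[3L] + 3 * cos(theta))
  r_out <- 3 + runif(60, 0.1, 0.4)
  theta2 <- runif(60, 0, 0.4 * pi); phi2 <- runif(60, 0, 2 * pi)
  outside <- cbind(cen[1L] + r_out * sin(theta2) * cos(phi2),
                   cen[2L] + r_out * sin(theta2) * sin(phi2),
                   cen[3L] + r_out * cos(theta2))
  c_stance <- estimate_ball_center(on_sphere, 3)
  c_all <- estimate_ball_center(rbind(on_sphere, outside), 3)
  expect_lt(sqrt(sum((c_all - c_stance)^2)), 1e-3)
})

test_that("penalized fit matches the unpenalized oracle when no point is inside", {
  set.seed(53)
  cen <- c(0.2, 0.1, -3.5)
  # a full-sphere shell uniformly 0.05 mm outside the ball: the
  # unpenalized optimum sits at the shell center with every residual
  # positive, so the penalized and unpenalized cost surfaces coincide
  # around it (a one-sided cap would pull the unpenalized optimum until
  # points fall inside, where the estimators legitimately differ)
  u <- runif(120, -1, 1); phi <- runif(120, 0, 2 * pi)
  r <- 3.05
  pts <- cbind(cen[1L] + r * sqrt(1 - u^2) * cos(phi),
               cen[2L] + r * sqrt(1 - u^2) * sin(phi),
               cen[3L] + r * u)
  ours <- estimate_ball_center(pts, 3)
  oracle <- oracle_sphere_center(pts, 3, colMeans(pts) - c(0, 0, 3))
  expect_lt(sqrt(sum((ours - oracle)^2)), 1e-6)
})

test_that("the asymmetric penalty pushes the center away from inside points", {
  set.seed(54)
  cen <- c(0, 0, -4)
  theta <- runif(150, 0, 0.4 * pi); phi <- runif(150, 0, 2 * pi)
  pts <- cbind(cen[1L] + 3 * sin(theta) * cos(phi),
               cen[2L] + 3 * sin(theta) * sin(phi),
               cen[3L] + 3 * cos(theta))
  # force one point deep inside the true sphere
  pts[1L, ] <- cen + c(0, 0, 2.2)
  c_pen <- estimate_ball_center(pts, 3)
  c_ora <- oracle_sphere_center(pts, 3, colMeans(pts) - c(0, 0, 3))
  pen_cost <- function(cenx) {
    d <- sqrt(rowSums(sweep(pts, 2L, cenx)^2)) - 3
    sum(ifelse(d < 0, 100, 1) * d^2)
  }
  expect_lt(pen_cost(c_pen), pen_cost(c_ora))
  # the offending point ends up less deeply inside under the penalized fit
  expect_gt(sqrt(sum((pts[1L, ] - c_pen)^2)), sqrt(sum((pts[1L, ] - c_ora)^2)))
})

test_that("degenerate tip clouds are rejected", {
  line <- cbind(seq(0, 1, length.out = 30), 0, 0)
  expect_error(estimate_ball_center(line, 3), "collinear")
  expect_error(estimate_ball_center(line[1:3, ], 3), "at least 4")
})

test_that("noiseless synthetic gait gives exact labels and events", {
  sc <- fixture_scenario(noise = 0)
  tips <- lapply(sc$keypoints, function(a) a[, "Tar", ])
  cen <- estimate_ball_center(do.call(rbind, tips), radius = sc$ball$radius)
  ph <- detect_phases(tips, cen, radius = sc$ball$radius)
  for (leg in names(tips)) {
    expect_identical(ph$legs[[leg]]$stance, unname(sc$stance[, leg]))
    ev <- ph$legs[[leg]]$events
    truth <- diff(sc$stance[, leg])
    expect_identical(ev$frame, which(truth != 0L) + 1L)
    expect_identical(ev$type,
                     ifelse(truth[truth != 0L] > 0L, "touchdown", "liftoff"))
    # event parity: lift-offs and touchdowns alternate
    expect_lte(abs(sum(ev$type == "liftoff") - sum(ev$type == "touchdown")), 1L)
  }
})

test_that("labels stay above 99 percent agreement at 5 um keypoint noise", {
  sc <- fixture_scenario(noise = 5)
  tips <- lapply(sc$keypoints, function(a) a[, "Tar", ])
  cen <- estimate_ball_center(do.call(rbind, tips), radius = sc$ball$radius)
  ph <- detect_phases(tips, cen, radius = sc$ball$radius)
  for (leg in names(tips)) {
    expect_gte(mean(ph$legs[[leg]]$stance == sc$stance[, leg]), 0.99)
  }
})

test_that("a leg that never touches yields all-swing and no events", {
  pts <- matrix(rep(c(0, 0, 10), each = 50), 50L, 3L)
  ph <- detect_phases(pts, center = c(0, 0, 0), radius = 3)
  expect_false(any(ph$legs[[1L]]$stance))
  expect_identical(nrow(ph$legs[[1L]]$events), 0L)
  expect_error(detect_phases(pts, c(0, 0, 0), radius = 3, threshold = 2),
               ">= ball radius")
})

test_that("debouncing removes single-frame label glitches", {
  d <- rep(c(2.9, 3.2), times = c(30, 30))
  d[15] <- 3.2                          # one-frame glitch inside stance
  pts <- cbind(0, 0, d)
  ph <- detect_phases(pts, c(0, 0, 0), radius = 3, threshold = 3.05,
                      min_duration = 3L)
  expect_true(all(ph$legs[[1L]]$stance[1:30]))
})

test_that("phase normalization is exact for linear and constant series", {
  stance <- rep(c(FALSE, TRUE, FALSE, TRUE, FALSE), times = c(5, 40, 30, 40, 5))
  ph <- structure(list(legs = list(leg = list(stance = stance)),
                       center = c(0, 0, 0), radius = 3, threshold = 3.05),
                  class = "step_phases")
  ramp <- seq_along(stance) * 0.5
  out <- normalize_phase(ramp, ph, "leg")
  expect_identical(dim(out$stance), c(2L, 100L))
  for (s in 1:2) {
    expect_equal(out$stance[s, ], seq(out$stance[s, 1L], out$stance[s, 100L],
                                      length.out = 100L), tolerance = 1e-12)
  }
  const <- normalize_phase(rep(7, length(stance)), ph, "leg")
  expect_true(all(const$stance == 7))
  expect_true(all(const$swing == 7))
})

test_that("an interval of exactly 100 frames resamples to itself", {
  stance <- rep(c(FALSE, TRUE, FALSE), times = c(10, 100, 10))
  ph <- structure(list(legs = list(leg = list(stance = stance)),
                       center = c(0, 0, 0), radius = 3, threshold = 3.05),
                  class = "step_phases")
  y <- rnorm(length(stance))
  out <- normalize_phase(y, ph, "leg")
  expect_equal(out$stance[1L, ], y[11:110], tolerance = 1e-12)
})

test_that("incomplete boundary intervals are dropped, short ones warned", {
  stance <- rep(c(TRUE, FALSE, TRUE, FALSE, TRUE), times = c(10, 1, 20, 10, 10))
  ph <- structure(list(legs = list(leg = list(stance = stance)),
                       center = c(0, 0, 0), radius = 3, threshold = 3.05),
                  class = "step_phases")
  expect_warning(out <- normalize_phase(seq_along(stance), ph, "leg"),
                 "shorter than 2")
  # boundary stance runs (first and last) are incomplete and excluded
  expect_identical(dim(out$stance), c(1L, 100L))
})
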