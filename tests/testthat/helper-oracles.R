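# Shared fixtures and independent oracles for the test suite.  Oracles are
# deliberately written against the public chain fields (reference axes,
# centers, keypoints) and never touch the Denavit-Hartenberg machinery they
# are used to check.

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# -- independent sequential axis-angle (Rodrigues) forward kinematics ------
rodrigues_rotate <- function(pts, axis, angle, center) {
  k <- axis / sqrt(sum(axis^2))
  one <- is.null(dim(pts))
  if (one) pts <- matrix(pts, nrow = 1L)
  p <- sweep(pts, 2L, center)
  kx <- p %*% k
  crx <- cbind(k[2L] * p[, 3L] - k[3L] * p[, 2L],
               k[3L] * p[, 1L] - k[1L] * p[, 3L],
               k[1L] * p[, 2L] - k[2L] * p[, 1L])
  out <- sweep(p * cos(angle) + crx * sin(angle) +
                 outer(as.vector(kx) * (1 - cos(angle)), k), 2L, -center)
  if (one) out[1L, ] else out
}

oracle_fk <- function(chain, ang_deg, tarsus_length = chain$tarsus_length) {
  axes <- chain$axes
  centers <- chain$centers
  kp <- chain$keypoints_ref
  u <- kp["Tar", ] - kp["TiTar", ]
  kp["Tar", ] <- kp["TiTar", ] + tarsus_length * u / sqrt(sum(u^2))
  kp_frame <- c(4L, 7L, 10L, 13L, 15L)
  for (i in 1:14) {
    phi <- ang_deg[i] * pi / 180
    if (phi == 0) next
    ax <- axes[i, ]; c0 <- centers[i, ]
    mv <- which(kp_frame > i)
    kp[mv, ] <- rodrigues_rotate(kp[mv, , drop = FALSE], ax, phi, c0)
    if (i < 14L) {
      idx <- (i + 1L):14L
      centers[idx, ] <- rodrigues_rotate(centers[idx, , drop = FALSE], ax, phi, c0)
      K <- ax / sqrt(sum(ax^2))
      Km <- matrix(c(0, K[3L], -K[2L], -K[3L], 0, K[1L], K[2L], -K[1L], 0), 3L, 3L)
      R <- diag(3L) + sin(phi) * Km + (1 - cos(phi)) * (Km %*% Km)
      axes[idx, ] <- axes[idx, , drop = FALSE] %*% t(R)
    }
  }
  kp
}

# -- independent lens-distortion polynomial oracle -------------------------
oracle_distort_pixel <- function(point3, cam) {
  pc <- as.vector(cam$rotation %*% point3 + cam$translation)
  x <- pc[1L] / pc[3L]; y <- pc[2L] / pc[3L]
  k1 <- cam$radial[1L]; k2 <- cam$radial[2L]; k3 <- cam$radial[3L]
  p1 <- cam$tangential[1L]; p2 <- cam$tangential[2L]
  r2 <- x^2 + y^2
  xd <- x * (1 + k1 * r2 + k2 * r2^2 + k3 * r2^3) +
    2 * p1 * x * y + p2 * (r2 + 2 * x^2)
  yd <- y * (1 + k1 * r2 + k2 * r2^2 + k3 * r2^3) +
    p1 * (r2 + 2 * y^2) + 2 * p2 * x * y
  c(cam$focal[1L] * xd + cam$principal_point[1L],
    cam$focal[2L] * yd + cam$principal_point[2L])
}

# -- unpenalized least-squares sphere-center oracle ------------------------
oracle_sphere_center <- function(pts, radius, start) {
  cost <- function(cen) sum((sqrt(rowSums(sweep(pts, 2L, cen)^2)) - radius)^2)
  grad <- function(cen) {
    diffs <- sweep(pts, 2L, cen)
    dist <- sqrt(rowSums(diffs^2))
    -2 * colSums((dist - radius) / pmax(dist, 1e-12) * diffs)
  }
  stats::optim(start, cost, gr = grad, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-15))$par
}

# -- cached fixtures -------------------------------------------------------
.fixture_env <- new.env(parent = emptyenv())

fixture_fly <- function(seed = 1L, obliquity = 15) {
  key <- paste0("fly_", seed, "_", obliquity)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- make_synthetic_fly(seed = seed, obliquity = obliquity)
  }
  .fixture_env[[key]]
}

fixture_chain <- function(leg = "R2", seed = 1L, obliquity = 15,
                          straightened = TRUE, ...) {
  key <- paste0("chain_", leg, "_", seed, "_", obliquity, "_", straightened)
  if (is.null(.fixture_env[[key]])) {
    ch <- build_chain(fixture_fly(seed, obliquity), leg, ...)
    if (straightened) ch <- straighten_initial_posture(ch)
    .fixture_env[[key]] <- ch
  }
  .fixture_env[[key]]
}

fixture_scenario <- function(noise = 0, n_steps = 3L,
                             legs = c("R1", "L1", "R2", "L2", "R3", "L3")) {
  key <- paste0("scen_", noise, "_", n_steps, "_", paste(legs, collapse = ""))
  if (is.null(.fixture_env[[key]])) {
    chains <- lapply(legs, function(l) fixture_chain(l))
    names(chains) <- legs
    .fixture_env[[key]] <- simulate_walking(chains, n_steps = n_steps,
                                            seed = 42L, noise_sigma_um = noise)
  }
  .fixture_env[[key]]
}

# small helper: a simple 3-camera rig in general position, no distortion
fixture_plain_rig <- function(n = 3L) {
  make_camera_rig(n_cameras = n, radial = c(0, 0, 0), tangential = c(0, 0))
}

expand_full_angles <- function(chain, named_deg) {
  ang <- setNames(numeric(14L), chain$dofs$dof)
  ang[names(named_deg)] <- named_deg
  ang
}

random_interior_angles <- function(chain, frac = 0.4) {
  mob <- which(chain$dofs$mobile)
  ang <- setNames(numeric(14L), chain$dofs$dof)
  for (k in mob) {
    ang[k] <- runif(1L, chain$dofs$lo_deg[k] * frac, chain$dofs$hi_deg[k] * frac)
  }
  ang
}
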