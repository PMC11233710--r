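# Inverse kinematics: box-bounded weighted nonlinear least squares fitting
# of a chain's forward kinematics to tracked keypoint positions.

#' Default keypoint weights for the fitting cost
#'
#' The distances of the TrFe, FeTi and TiTar keypoints are weighted more
#' strongly than the others for the front legs (1.5, 2.0, 1.5) and the
#' middle legs (1.25, 1.5, 1.25); all other weights are 1.  Weights
#' multiply the residual distances before squaring.
#'
#' @param leg leg identifier.
#' @return named numeric of length 5 (CxTr, TrFe, FeTi, TiTar, Tar).
#' @export
default_weights <- function(leg) {
  w <- stats::setNames(rep(1, 5L), KEYPOINTS)
  pair <- leg_pair(leg)
  if (pair == "front") w[c("TrFe", "FeTi", "TiTar")] <- c(1.5, 2.0, 1.5)
  if (pair == "middle") w[c("TrFe", "FeTi", "TiTar")] <- c(1.25, 1.5, 1.25)
  w
}

#' Solver controls for the inverse-kinematic fit
#'
#' The fit uses the box-bounded quasi-Newton PORT solver.  The `1e-3`
#' termination criterion on changes of the cost function maps onto the
#' solver's relative function-convergence tolerance (`rel.tol`); the step
#' and gradient criteria are left at the solver's own (tighter) defaults,
#' because PORT's relative step test has different semantics from a
#' trust-region step bound and at `1e-3` would terminate about an order of
#' magnitude short of the positional accuracy the cost criterion itself
#' permits (see the methods vignette).  The iteration cap is 100 times the
#' number of mobile DOFs.
#'
#' @param tol relative cost-change termination tolerance.
#' @param max_iter_per_dof iteration cap multiplier.
#' @return list of controls consumed by [fit_frame()].
#' @export
ik_control <- function(tol = 1e-3, max_iter_per_dof = 100L) {
  list(tol = tol, max_iter_per_dof = max_iter_per_dof)
}

ik_cost_fn <- function(chain, targets, w2) {
  mob <- which(chain$dofs$mobile)
  force(targets); force(w2)
  function(par) {
    ang <- numeric(14L)
    ang[mob] <- par
    pts <- fk_keypoints_rad(chain, ang)
    sum(w2 * rowSums((pts - targets)^2))
  }
}

#' Fit a chain to a single tracked leg posture
#'
#' Minimizes the weighted sum of squared distances between the model's and
#' the tracked CxTr, TrFe, FeTi, TiTar and Tar positions over the mobile
#' DOF angles, subject to the chain's box bounds, starting from `init`.
#' The tarsus length should already have been set from the tracked tarsus
#' for this frame (see [fit_sequence()], which does this per frame).
#'
#' @param chain a `kinematic_chain`.
#' @param targets 5 x 3 matrix of tracked keypoint positions (mm, body
#'   coordinates; rows CxTr, TrFe, FeTi, TiTar, Tar).
#' @param init initial mobile-DOF angles in degrees (named or in chain
#'   order); defaults to all zero.
#' @param weights per-keypoint weights (default [default_weights()]).
#' @param control see [ik_control()].
#' @return list with `angles_deg` (named), `residuals_um` (per keypoint),
#'   `error_um` (summed model error), `iterations`, `converged`, `valid`,
#'   `active_bounds` (logical per mobile DOF), and `objective`.
#' @export
fit_frame <- function(chain, targets, init = NULL,
                      weights = default_weights(chain$leg),
                      control = ik_control()) {
  stopifnot(inherits(chain, "kinematic_chain"))
  targets <- as.matrix(targets)
  if (nrow(targets) != 5L) stop("targets must have 5 rows (CxTr..Tar)")
  mob <- which(chain$dofs$mobile)
  nm <- chain$dofs$dof[mob]
  if (anyNA(targets) || any(!is.finite(targets))) {
    return(list(angles_deg = stats::setNames(rep(NA_real_, length(mob)), nm),
                residuals_um = stats::setNames(rep(NA_real_, 5L), KEYPOINTS),
                error_um = NA_real_, iterations = 0L, converged = FALSE,
                valid = FALSE,
                active_bounds = stats::setNames(rep(FALSE, length(mob)), nm),
                objective = NA_real_))
  }
  w <- rep(1, 5L)
  if (!is.null(weights)) {
    if (!is.null(names(weights))) w[match(names(weights), KEYPOINTS)] <- weights
    else w <- rep_len(weights, 5L)
  }
  lo <- deg2rad(chain$dofs$lo_deg[mob])
  hi <- deg2rad(chain$dofs$hi_deg[mob])
  if (is.null(init)) {
    par0 <- numeric(length(mob))
  } else if (!is.null(names(init))) {
    par0 <- numeric(length(mob))
    idx <- match(names(init), nm)
    if (anyNA(idx)) stop("init names unknown among mobile DOFs: ",
                         paste(names(init)[is.na(idx)], collapse = ", "))
    par0[idx] <- deg2rad(as.numeric(init))
  } else {
    par0 <- deg2rad(as.numeric(rep_len(init, length(mob))))
  }
  par0 <- pmin(pmax(par0, lo), hi)
  fn <- ik_cost_fn(chain, targets, w^2)
  res <- stats::nlminb(par0, fn, lower = lo, upper = hi,
                       control = list(
                         iter.max = control$max_iter_per_dof * length(mob),
                         eval.max = 50L * control$max_iter_per_dof * length(mob),
                         rel.tol = control$tol))
  par <- pmin(pmax(res$par, lo), hi)
  ang14 <- numeric(14L); ang14[mob] <- par
  pts <- fk_keypoints_rad(chain, ang14)
  dists <- sqrt(rowSums((pts - targets)^2))
  # PORT reports "false convergence (8)" when started at (or reaching) a
  # point whose small predicted reduction it cannot verify -- e.g., an
  # exact zero-residual optimum; treat that as converged
  ok <- res$convergence == 0L || grepl("false convergence", res$message)
  list(angles_deg = stats::setNames(rad2deg(par), nm),
       residuals_um = stats::setNames(dists * 1000, KEYPOINTS),
       error_um = sum(dists) * 1000,
       iterations = res$iterations,
       converged = ok,
       valid = TRUE,
       active_bounds = stats::setNames(par <= lo + 1e-10 | par >= hi - 1e-10, nm),
       objective = res$objective)
}

#' Per-joint initialization of the first frame
#'
#' Proceeding from the most proximal joint outward, each joint's mobile DOF
#' angles are optimized in isolation against the tracked position of the
#' keypoint that joint most directly moves (ThCx -> CxTr, CxTr -> TrFe,
#' TrFe -> FeTi, FeTi -> TiTar, TiTar -> Tar), holding all other joints at
#' their current values.  The result, clipped into the bounds, is used as
#' the start of the subsequent global fit.
#'
#' @inheritParams fit_frame
#' @return named vector of mobile-DOF angles in degrees.
#' @export
init_angles_per_joint <- function(chain, targets, control = ik_control()) {
  stopifnot(inherits(chain, "kinematic_chain"))
  targets <- as.matrix(targets)
  if (anyNA(targets)) stop("cannot initialize from targets with missing values")
  mob <- which(chain$dofs$mobile)
  lo <- deg2rad(chain$dofs$lo_deg)
  hi <- deg2rad(chain$dofs$hi_deg)
  target_kp <- c(ThCx = "CxTr", CxTr = "TrFe", TrFe = "FeTi",
                 FeTi = "TiTar", TiTar = "Tar")
  ang14 <- numeric(14L)
  for (joint in JOINTS) {
    jidx <- intersect(which(chain$dofs$joint == joint), mob)
    if (length(jidx) == 0L) next
    goal <- targets[target_kp[joint], ]
    fn <- function(p) {
      a <- ang14; a[jidx] <- p
      pt <- fk_keypoints_rad(chain, a)[target_kp[joint], ]
      sum((pt - goal)^2)
    }
    res <- stats::nlminb(ang14[jidx], fn, lower = lo[jidx], upper = hi[jidx],
                         control = list(iter.max = 100L * length(jidx),
                                        rel.tol = control$tol))
    ang14[jidx] <- pmin(pmax(res$par, lo[jidx]), hi[jidx])
  }
  stats::setNames(rad2deg(ang14[mob]), chain$dofs$dof[mob])
}

#' Fit a chain to a sequence of tracked leg postures
#'
#' The first valid frame is initialized per joint and then fitted globally;
#' every subsequent frame is warm-started from the previous solution (the
#' warm start is carried across invalid frames).  The tarsus length is
#' updated for every frame from the tracked TiTar-to-Tar distance before
#' fitting.
#'
#' @param chain a `kinematic_chain`.
#' @param targets frames x 5 x 3 array (or list of 5 x 3 matrices) of
#'   tracked keypoint positions (mm).
#' @param weights per-keypoint weights.
#' @param control see [ik_control()].
#' @return object of class `fit_result`: data.frame `angles` (frame x DOF,
#'   degrees), matrix `residuals_um`, vectors `error_um`, `converged`,
#'   `valid`, `iterations`, `tarsus_length`, and the chain.
#' @export
fit_sequence <- function(chain, targets, weights = default_weights(chain$leg),
                         control = ik_control()) {
  stopifnot(inherits(chain, "kinematic_chain"))
  if (is.list(targets)) {
    targets <- aperm(simplify2array(targets), c(3L, 1L, 2L))
  }
  n <- dim(targets)[1L]
  if (is.na(n) || n < 1L) stop("need at least one target frame")
  mob <- which(chain$dofs$mobile)
  nm <- chain$dofs$dof[mob]
  angles <- matrix(NA_real_, n, length(mob), dimnames = list(NULL, nm))
  residuals <- matrix(NA_real_, n, 5L, dimnames = list(NULL, KEYPOINTS))
  error_um <- rep(NA_real_, n)
  converged <- valid <- rep(FALSE, n)
  iterations <- integer(n)
  tarsus_len <- rep(NA_real_, n)
  warm <- NULL
  for (f in seq_len(n)) {
    tgt <- matrix(targets[f, , ], 5L, 3L, dimnames = list(KEYPOINTS, NULL))
    if (anyNA(tgt)) next
    L <- vnorm(tgt["Tar", ] - tgt["TiTar", ])
    ch_f <- set_tarsus_length(chain, L)
    tarsus_len[f] <- L
    if (is.null(warm)) warm <- init_angles_per_joint(ch_f, tgt, control)
    res <- fit_frame(ch_f, tgt, init = warm, weights = weights,
                     control = control)
    angles[f, ] <- res$angles_deg
    residuals[f, ] <- res$residuals_um
    error_um[f] <- res$error_um
    converged[f] <- res$converged
    valid[f] <- TRUE
    iterations[f] <- res$iterations
    warm <- res$angles_deg
  }
  if (!any(valid)) stop("all frames invalid: nothing to fit")
  structure(list(angles = angles, residuals_um = residuals,
                 error_um = error_um, converged = converged, valid = valid,
                 iterations = iterations, tarsus_length = tarsus_len,
                 leg = chain$leg, chain = chain),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>", x$leg, ":", sum(x$valid), "of", length(x$valid),
      "frames fitted; mean model error",
      sprintf("%.2f um", mean(x$error_um, na.rm = TRUE)), "\n")
  invisible(x)
}
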