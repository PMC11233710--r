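# Swing/stance phase detection on the spherical treadmill: ball-center
# estimation, distance thresholding, step events, and phase-time
# normalization.

#' Estimate the treadmill-ball center from tarsus-tip positions
#'
#' Minimizes `sum(w_i * (||p_i - c|| - radius)^2)` over the center `c`,
#' where `w_i = 100` for tips closer to the center than the radius and 1
#' otherwise.  The asymmetric penalty keeps the fitted sphere outside the
#' cloud of tarsus tips (tips cannot be inside the ball).  The optimization
#' is multi-started from the tip centroid and from the centroid shifted by
#' one radius along -z.
#'
#' @param tarsus_tips n x 3 matrix of tarsus-tip positions from all legs
#'   and frames (mm).
#' @param radius ball radius in mm (3 mm for the standard setup).
#' @param penalty penalty factor for tips inside the sphere.
#' @return length-3 ball-center estimate (mm).
#' @export
estimate_ball_center <- function(tarsus_tips, radius = 3, penalty = 100) {
  pts <- as.matrix(tarsus_tips)
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  if (nrow(pts) < 4L) stop("need at least 4 tarsus-tip positions")
  sv <- svd(sweep(pts, 2L, colMeans(pts)))
  if (sv$d[3L] < 1e-9 * max(sv$d[1L], 1) && nrow(pts) > 3L) {
    # near-coplanar clouds leave the center direction unidentified only if
    # the sphere is also locally flat; warn rather than refuse when the
    # curvature is resolvable, refuse when the spread is degenerate
    if (sv$d[2L] < 1e-9 * max(sv$d[1L], 1)) {
      stop("tarsus tips are collinear: ball center unidentifiable")
    }
  }
  cost <- function(cen) {
    d <- sqrt(rowSums(sweep(pts, 2L, cen)^2)) - radius
    w <- ifelse(d < 0, penalty, 1)
    sum(w * d^2)
  }
  grad <- function(cen) {
    diffs <- sweep(pts, 2L, cen)
    dist <- sqrt(rowSums(diffs^2))
    d <- dist - radius
    w <- ifelse(d < 0, penalty, 1)
    -2 * colSums(w * d / pmax(dist, 1e-12) * diffs)
  }
  centroid <- colMeans(pts)
  starts <- list(centroid, centroid - c(0, 0, radius))
  best <- NULL
  for (s in starts) {
    r <- stats::optim(s, cost, gr = grad, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-15))
    if (is.null(best) || r$value < best$value) best <- r
  }
  as.numeric(best$par)
}

#' Classify swing and stance phases by distance thresholding
#'
#' A leg is in stance in a frame when its tarsus-tip distance to the ball
#' center is at or below the threshold.  Touchdown events are swing-to-
#' stance transitions, lift-offs stance-to-swing.  Optional debouncing
#' removes phases shorter than `min_duration` frames (mimicking manual
#' correction of single-frame misclassifications); it is off by default.
#'
#' @param tarsus_tips n x 3 matrix (one leg's tip positions, mm), or a
#'   named list of such matrices for several legs.
#' @param center ball center (mm).
#' @param radius ball radius (mm).
#' @param threshold stance threshold distance (mm, >= radius); scalar or
#'   named per leg.  Default: radius + 0.05 mm.
#' @param min_duration minimum phase duration in frames (0 = no debounce).
#' @return an object of class `step_phases`: per leg, logical `stance`
#'   vector and data.frame `events` (`frame`, `type` in
#'   `c("liftoff", "touchdown")`); plus `center`, `radius`, `threshold`.
#' @export
detect_phases <- function(tarsus_tips, center, radius = 3,
                          threshold = radius + 0.05, min_duration = 0L) {
  if (!is.list(tarsus_tips)) tarsus_tips <- list(leg = tarsus_tips)
  if (any(threshold < radius)) stop("threshold must be >= ball radius")
  thr <- rep_len(threshold, length(tarsus_tips))
  if (!is.null(names(threshold)) && !is.null(names(tarsus_tips))) {
    thr <- threshold[names(tarsus_tips)]
  }
  legs <- lapply(seq_along(tarsus_tips), function(i) {
    pts <- as.matrix(tarsus_tips[[i]])
    d <- sqrt(rowSums(sweep(pts, 2L, as.numeric(center))^2))
    stance <- d <= thr[i]
    if (min_duration > 1L) stance <- debounce_labels(stance, min_duration)
    tr <- diff(stance)
    events <- data.frame(
      frame = which(tr != 0L) + 1L,
      type = ifelse(tr[tr != 0L] > 0L, "touchdown", "liftoff"))
    list(stance = stance, distance = d, events = events)
  })
  names(legs) <- names(tarsus_tips)
  structure(list(legs = legs, center = as.numeric(center), radius = radius,
                 threshold = thr),
            class = "step_phases")
}

debounce_labels <- function(stance, min_duration) {
  r <- rle(stance)
  # absorb short runs into the preceding phase (interior runs only)
  for (i in seq_along(r$lengths)) {
    if (r$lengths[i] < min_duration && i > 1L && i < length(r$lengths)) {
      r$values[i] <- r$values[i - 1L]
    }
  }
  inverse.rle(within_rle_merge(r))
}

within_rle_merge <- function(r) {
  keep <- c(TRUE, r$values[-1L] != r$values[-length(r$values)])
  lengths <- as.integer(tapply(r$lengths, cumsum(keep), sum))
  list(lengths = lengths, values = r$values[keep])
}

#' @export
print.step_phases <- function(x, ...) {
  cat("<step_phases>", length(x$legs), "legs, ball center",
      paste(signif(x$center, 4), collapse = ", "), "mm, radius",
      x$radius, "mm\n")
  for (nm in names(x$legs)) {
    cat("  ", nm, ": ", sum(x$legs[[nm]]$stance), "/",
        length(x$legs[[nm]]$stance), " stance frames, ",
        nrow(x$legs[[nm]]$events), " events\n", sep = "")
  }
  invisible(x)
}

# complete phase intervals of one type: list of index ranges strictly
# inside the recording (incomplete boundary intervals dropped)
complete_intervals <- function(stance, phase = c("stance", "swing")) {
  phase <- match.arg(phase)
  lab <- if (phase == "stance") stance else !stance
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & starts > 1L & ends < length(lab)
  Map(function(s, e) s:e, starts[keep], ends[keep])
}

#' Normalize per-frame series onto the step phases
#'
#' Every complete swing and stance interval is linearly interpolated onto
#' 100 samples spanning normalized phase time 0 to 1; incomplete intervals
#' at the recording boundaries are dropped, as are intervals shorter than
#' two frames (with a warning).
#'
#' @param series numeric vector (one value per frame) or n x k matrix.
#' @param phases a [detect_phases()] result.
#' @param leg which leg of `phases` to use.
#' @param n_samples number of samples per normalized interval.
#' @return list with `stance` and `swing`: arrays of dimension
#'   steps x n_samples (x k for matrix input).
#' @export
normalize_phase <- function(series, phases, leg = names(phases$legs)[1L],
                            n_samples = 100L) {
  stopifnot(inherits(phases, "step_phases"))
  stance <- phases$legs[[leg]]$stance
  if (is.null(stance)) stop("unknown leg: ", leg)
  mat <- as.matrix(series)
  if (nrow(mat) != length(stance)) stop("series length does not match phases")
  grid <- seq(0, 1, length.out = n_samples)
  out <- list()
  for (phase in c("stance", "swing")) {
    ivs <- complete_intervals(stance, phase)
    short <- vapply(ivs, length, integer(1L)) < 2L
    if (any(short)) {
      warning(sum(short), " ", phase, " interval(s) shorter than 2 frames dropped")
      ivs <- ivs[!short]
    }
    res <- array(NA_real_, c(length(ivs), n_samples, ncol(mat)))
    for (s in seq_along(ivs)) {
      x <- seq(0, 1, length.out = length(ivs[[s]]))
      for (k in seq_len(ncol(mat))) {
        res[s, , k] <- stats::approx(x, mat[ivs[[s]], k], xout = grid)$y
      }
    }
    out[[phase]] <- if (ncol(mat) == 1L) res[, , 1L, drop = TRUE] else res
    if (length(ivs) == 1L && ncol(mat) == 1L) {
      out[[phase]] <- matrix(out[[phase]], 1L, n_samples)
    }
  }
  out
}
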