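# Joint DOF angle constraints (degrees, right legs).  Signs of yaw and roll
# bounds are inverted for left legs; pitch bounds are side-invariant.

JOINTS <- c("ThCx", "CxTr", "TrFe", "FeTi", "TiTar")
DOF_KINDS <- c("yaw", "pitch", "roll")
KEYPOINTS <- c("CxTr", "TrFe", "FeTi", "TiTar", "Tar")

# full 14-DOF ordering of a leg chain: 3 DOFs for ThCx..FeTi, yaw+pitch for
# TiTar (the tibia-tarsus joint has no roll DOF)
dof_table_skeleton <- function() {
  joint <- c(rep(JOINTS[1:4], each = 3L), "TiTar", "TiTar")
  kind <- c(rep(DOF_KINDS, 4L), "yaw", "pitch")
  data.frame(joint = joint, kind = kind,
             dof = paste(joint, kind, sep = "-"),
             stringsAsFactors = FALSE)
}

.bounds_oblique <- list(
  front = list(
    ThCx  = list(yaw = c(-70, 70),   pitch = c(-33, 147),  roll = c(-160, 50)),
    CxTr  = list(yaw = c(-20, 160),  pitch = c(-108, 72),  roll = c(-120, 120)),
    TrFe  = list(yaw = c(-90, 90),   pitch = c(-108, 72),  roll = c(-90, 90)),
    FeTi  = list(yaw = c(-20, 145),  pitch = c(-75, 75),   roll = c(-90, 90)),
    TiTar = list(yaw = c(-60, 120),  pitch = c(-75, 75))),
  middle = list(
    ThCx  = list(yaw = c(-90, 60),   pitch = c(-40, 140),  roll = c(-90, 90)),
    CxTr  = list(yaw = c(-140, 10),  pitch = c(-54, 126),  roll = c(-90, 90)),
    TrFe  = list(yaw = c(-110, 110), pitch = c(-123, 57),  roll = c(-110, 90)),
    FeTi  = list(yaw = c(0, 170),    pitch = c(-90, 90),   roll = c(-90, 90)),
    TiTar = list(yaw = c(-10, 140),  pitch = c(-64, 116))),
  hind = list(
    ThCx  = list(yaw = c(-90, 60),   pitch = c(-39, 141),  roll = c(-100, 100)),
    CxTr  = list(yaw = c(-110, 30),  pitch = c(-121, 59),  roll = c(-90, 110)),
    TrFe  = list(yaw = c(-90, 90),   pitch = c(-54, 126),  roll = c(-90, 90)),
    FeTi  = list(yaw = c(10, 180),   pitch = c(-103, 77),  roll = c(-90, 90)),
    TiTar = list(yaw = c(-5, 90),    pitch = c(-85, 95))))

.bounds_orthogonalized <- list(
  front = list(
    ThCx  = list(yaw = c(-70, 90),   pitch = c(-75, 75),   roll = c(-220, 0)),
    CxTr  = list(yaw = c(-180, 60),  pitch = c(-75, 75),   roll = c(-90, 120)),
    TrFe  = list(yaw = c(-90, 90),   pitch = c(-75, 75),   roll = c(-90, 90)),
    FeTi  = list(yaw = c(-20, 145),  pitch = c(-75, 75),   roll = c(-90, 90)),
    TiTar = list(yaw = c(-60, 120),  pitch = c(-75, 75))),
  middle = list(
    ThCx  = list(yaw = c(-75, 75),   pitch = c(-20, 60),   roll = c(-75, 75)),
    CxTr  = list(yaw = c(-20, 130),  pitch = c(-75, 75),   roll = c(-90, 90)),
    TrFe  = list(yaw = c(-90, 90),   pitch = c(-75, 75),   roll = c(-110, 90)),
    FeTi  = list(yaw = c(-170, 10),  pitch = c(-90, 90),   roll = c(-90, 90)),
    TiTar = list(yaw = c(0, 90),     pitch = c(-60, 60))),
  hind = list(
    ThCx  = list(yaw = c(-90, 90),   pitch = c(-75, 75),   roll = c(-45, 130)),
    CxTr  = list(yaw = c(-20, 150),  pitch = c(-75, 75),   roll = c(-90, 90)),
    TrFe  = list(yaw = c(-90, 90),   pitch = c(-75, 75),   roll = c(-45, 45)),
    FeTi  = list(yaw = c(-150, 20),  pitch = c(-75, 75),   roll = c(-90, 90)),
    TiTar = list(yaw = c(-90, 90),   pitch = c(-75, 75))))

#' Leg pair of a leg identifier
#'
#' Legs are identified as `R1`, `L1` (front), `R2`, `L2` (middle), `R3`,
#' `L3` (hind).
#' @param leg leg identifier.
#' @return `"front"`, `"middle"` or `"hind"`.
#' @export
leg_pair <- function(leg) {
  side_of_leg(leg)  # validates
  c("front", "middle", "hind")[as.integer(substr(leg, 2L, 2L))]
}

side_of_leg <- function(leg) {
  if (!is.character(leg) || length(leg) != 1L ||
      !grepl("^[RL][123]$", leg)) {
    stop("leg must be one of R1, L1, R2, L2, R3, L3")
  }
  if (substr(leg, 1L, 1L) == "R") "right" else "left"
}

#' Default joint DOF angle constraints
#'
#' Returns the per-DOF angle bounds (degrees) used by the inverse-kinematic
#' solver to exclude unnatural leg postures, for the condyle-based (oblique)
#' or the orthogonalized model variant.  Bounds are tabulated for right
#' legs; for a left leg the signs of the yaw and roll bounds are inverted
#' (and the interval endpoints swapped), while pitch bounds are unchanged.
#'
#' @param leg leg identifier (`R1`, `L1`, ...).
#' @param model `"oblique"` (condyle-derived axes) or `"orthogonalized"`.
#' @return data.frame with columns `joint`, `kind`, `dof`, `lo_deg`,
#'   `hi_deg` in chain order (14 rows).
#' @export
dof_bounds <- function(leg, model = c("oblique", "orthogonalized")) {
  model <- match.arg(model)
  pair <- leg_pair(leg)
  side <- side_of_leg(leg)
  tab <- if (model == "oblique") .bounds_oblique else .bounds_orthogonalized
  tab <- tab[[pair]]
  skel <- dof_table_skeleton()
  lo <- hi <- numeric(nrow(skel))
  for (i in seq_len(nrow(skel))) {
    b <- tab[[skel$joint[i]]][[skel$kind[i]]]
    if (side == "left" && skel$kind[i] %in% c("yaw", "roll")) b <- -rev(b)
    lo[i] <- b[1L]; hi[i] <- b[2L]
  }
  cbind(skel, lo_deg = lo, hi_deg = hi)
}

#' Default DOF mobility configuration
#'
#' The reference configuration mobilizes all three thorax-coxa DOFs, the
#' coxa-trochanter yaw, the femur-tibia yaw, and the tibia-tarsus yaw and
#' pitch, with the trochanter-femur joint fully arrested.  The final
#' front-leg configuration additionally mobilizes the trochanter-femur roll.
#'
#' @param leg leg identifier.
#' @param config `"reference"` or `"final"`.
#' @return named list mapping joint name to character vector of mobile DOF
#'   kinds, suitable for [build_chain()].
#' @export
default_dof_config <- function(leg, config = c("reference", "final")) {
  config <- match.arg(config)
  cfg <- list(ThCx = c("yaw", "pitch", "roll"), CxTr = "yaw",
              FeTi = "yaw", TiTar = c("yaw", "pitch"))
  if (config == "final" && leg_pair(leg) == "front") cfg$TrFe <- "roll"
  cfg
}

# validate a mobility config and return the logical 14-vector in chain order
mobility_vector <- function(dof_config) {
  skel <- dof_table_skeleton()
  mob <- rep(FALSE, nrow(skel))
  for (joint in names(dof_config)) {
    if (!joint %in% JOINTS) stop("unknown joint in dof_config: ", joint)
    for (kind in dof_config[[joint]]) {
      idx <- which(skel$joint == joint & skel$kind == kind)
      if (length(idx) != 1L) {
        stop("DOF does not exist in the chain: ", joint, "-", kind)
      }
      mob[idx] <- TRUE
    }
  }
  mob
}

#' Read / write a DOF configuration file
#'
#' JSON with, per leg, the list of mobile DOFs per joint and optional bounds
#' overrides: `{"R1": {"mobile": {"ThCx": ["yaw", ...]}, "bounds": {"ThCx-yaw": [lo, hi]}}}`.
#'
#' @param path file path.
#' @param config named list (per leg) as above.
#' @return `read_dof_config` returns the parsed list.
#' @export
read_dof_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @rdname read_dof_config
#' @export
write_dof_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
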