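#' Condyle landmark set
#'
#' Container for the anatomical landmarks that define the kinematic model:
#' for every leg and every joint (ThCx, CxTr, TrFe, FeTi, TiTar) the two
#' articulation condyles and the joint center, plus the tarsus tip per leg
#' and the body reference landmarks ThAp, lWH, rWH.  Coordinates are mm, in
#' an arbitrary rigid frame (e.g., the uCT scanner frame).
#'
#' @param legs named list (`R1`, `L1`, ...) of per-leg landmark lists, each
#'   with `joints` (named list of `list(condyle_a, condyle_b, center)`) and
#'   `tarsus_tip`.
#' @param body list with `ThAp`, `lWH`, `rWH` positions.
#' @return an object of class `condyle_landmarks`.
#' @export
condyle_landmarks <- function(legs, body) {
  stopifnot(is.list(legs), is.list(body),
            all(c("ThAp", "lWH", "rWH") %in% names(body)))
  for (leg in names(legs)) {
    side_of_leg(leg)
    jl <- legs[[leg]]$joints
    if (!all(JOINTS %in% names(jl))) {
      stop("leg ", leg, " is missing joints: ",
           paste(setdiff(JOINTS, names(jl)), collapse = ", "))
    }
    centers <- t(vapply(jl[JOINTS], function(j) as.numeric(j$center), numeric(3L)))
    for (joint in JOINTS) {
      j <- jl[[joint]]
      if (!all(c("condyle_a", "condyle_b", "center") %in% names(j))) {
        stop("leg ", leg, " joint ", joint, ": missing condyle landmark fields")
      }
      if (vnorm(as.numeric(j$condyle_a) - as.numeric(j$condyle_b)) < 1e-9) {
        stop("leg ", leg, " joint ", joint, ": condyles coincide")
      }
    }
    if (min(dist(rbind(centers, as.numeric(legs[[leg]]$tarsus_tip)))) < 1e-9) {
      stop("leg ", leg, ": joint centers along the leg must be pairwise distinct")
    }
  }
  structure(list(legs = legs, body = lapply(body[c("ThAp", "lWH", "rWH")],
                                            as.numeric)),
            class = "condyle_landmarks")
}

#' @export
print.condyle_landmarks <- function(x, ...) {
  cat("<condyle_landmarks>", length(x$legs), "legs:",
      paste(names(x$legs), collapse = ", "), "\n")
  invisible(x)
}

#' Mirror one leg's landmarks across the body sagittal plane
#'
#' The sagittal plane contains the body x and z axes and passes through the
#' ThAp; reflection maps a left-leg landmark set onto a valid right-leg set
#' and vice versa.
#'
#' @param landmarks a [condyle_landmarks()] set.
#' @param leg leg to mirror (e.g., `"L1"` to produce an `"R1"` set).
#' @param frame optional [compute_body_frame()]; computed from the body
#'   landmarks when omitted.
#' @return the mirrored per-leg landmark list (same structure as
#'   `landmarks$legs[[leg]]`).
#' @export
mirror_leg_landmarks <- function(landmarks, leg, frame = NULL) {
  stopifnot(inherits(landmarks, "condyle_landmarks"))
  if (is.null(frame)) {
    frame <- compute_body_frame(landmarks$body$ThAp, landmarks$body$lWH,
                                landmarks$body$rWH)
  }
  n <- frame$y_axis
  refl <- function(p) {
    p <- as.numeric(p)
    v <- p - frame$origin
    frame$origin + v - 2 * sum(v * n) * n
  }
  src <- landmarks$legs[[leg]]
  if (is.null(src)) stop("leg ", leg, " not present in landmark set")
  out <- src
  for (joint in names(src$joints)) {
    out$joints[[joint]] <- lapply(src$joints[[joint]], refl)
  }
  out$tarsus_tip <- refl(src$tarsus_tip)
  out
}

#' Read / write landmark JSON files
#'
#' Schema: `{"legs": {"R1": {"joints": {"ThCx": {"condyle_a": [...],
#' "condyle_b": [...], "center": [...]}, ...}, "tarsus_tip": [...]}, ...},
#' "body": {"ThAp": [...], "lWH": [...], "rWH": [...]}}`.
#'
#' @param path file path.
#' @param landmarks a [condyle_landmarks()] set.
#' @return `read_landmarks` returns a `condyle_landmarks` object.
#' @export
read_landmarks <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  legs <- lapply(raw$legs, function(lg) {
    list(joints = lapply(lg$joints, function(j) lapply(j, as.numeric)),
         tarsus_tip = as.numeric(lg$tarsus_tip))
  })
  condyle_landmarks(legs, lapply(raw$body, as.numeric))
}

#' @rdname read_landmarks
#' @export
write_landmarks <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "condyle_landmarks"))
  jsonlite::write_json(unclass(landmarks), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
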