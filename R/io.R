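# Tabular I/O for keypoint sequences.  3D keypoints travel as plain CSV
# with columns frame, leg, keypoint, x_mm, y_mm, z_mm; 2D observations as
# frame, camera_id, keypoint, x_px, y_px, valid.

#' Read / write 3D keypoint sequence tables
#'
#' @param path CSV file path.
#' @param keypoints named list (per leg) of frames x 5 x 3 arrays with
#'   keypoint dimension named `CxTr, TrFe, FeTi, TiTar, Tar`.
#' @return `read_keypoints3d` returns such a named list.
#' @export
read_keypoints3d <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "leg", "keypoint", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(tab))) {
    stop("keypoint table must have columns ", paste(need, collapse = ", "))
  }
  out <- list()
  for (leg in unique(tab$leg)) {
    sub <- tab[tab$leg == leg, ]
    frames <- sort(unique(sub$frame))
    arr <- array(NA_real_, c(length(frames), 5L, 3L),
                 dimnames = list(NULL, KEYPOINTS, c("x", "y", "z")))
    fi <- match(sub$frame, frames)
    ki <- match(sub$keypoint, KEYPOINTS)
    ok <- !is.na(ki)
    arr[cbind(fi[ok], ki[ok], 1L)] <- sub$x_mm[ok]
    arr[cbind(fi[ok], ki[ok], 2L)] <- sub$y_mm[ok]
    arr[cbind(fi[ok], ki[ok], 3L)] <- sub$z_mm[ok]
    out[[leg]] <- arr
  }
  out
}

#' @rdname read_keypoints3d
#' @export
write_keypoints3d <- function(keypoints, path) {
  rows <- lapply(names(keypoints), function(leg) {
    arr <- keypoints[[leg]]
    n <- dim(arr)[1L]
    do.call(rbind, lapply(seq_len(dim(arr)[2L]), function(k) {
      data.frame(frame = seq_len(n), leg = leg,
                 keypoint = dimnames(arr)[[2L]][k],
                 x_mm = arr[, k, 1L], y_mm = arr[, k, 2L], z_mm = arr[, k, 3L])
    }))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
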