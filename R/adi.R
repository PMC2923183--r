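# Phase B: the accumulative-difference-image (ADI) structure.  Differences
# between consecutive binary detection frames record, per pixel, the
# frames at which a target newly arrives there ("passage times", the V
# matrix).  Re-entries of a pixel are kept as a list, which strictly
# generalizes a single last-passage-time matrix and keeps loops
# representable.

#' Build the passage-time map from a detection stack
#'
#' For each frame `j = 1..M-1` and pixel `p`, a passage event `j` is stored
#' whenever `|det_j(p) - det_{j-1}(p)| > S` and `det_j(p) = 1`, i.e. when a
#' target newly occupies `p`.  Because the input is binary, any
#' `S` in `[0, 1)` yields the same map.  Departures (1 to 0) carry no
#' linkable arrival position and are dropped.  Frame-0 occupancy is kept
#' separately as the seed set.
#'
#' @param det A [detection_stack()] with at least 2 frames.
#' @param S Difference threshold in `[0, 1)`.
#' @return A `passage_map` with fields `passages` (list over linear pixel
#'   index, each a strictly increasing vector of 0-based frame indices),
#'   `seeds0` (matrix of 0-based frame-0 marks), `n_frames`, `dim`,
#'   `threshold_S` and `n_events`.
#' @export
build_passage_map <- function(det, S = 0.5) {
  stopifnot(inherits(det, "detection_stack"))
  if (det$n_frames < 2) stop("tracking requires at least 2 frames (M >= 2)")
  if (S < 0 || S >= 1) stop("S must lie in [0, 1)")
  h <- det$height; w <- det$width; M <- det$n_frames
  maps <- det$maps
  pix_all <- integer(0); frm_all <- integer(0)
  for (j in 2:M) {
    new_occ <- which(maps[, , j] & !maps[, , j - 1])
    if (length(new_occ)) {
      pix_all <- c(pix_all, new_occ)
      frm_all <- c(frm_all, rep.int(j - 1L, length(new_occ)))  # 0-based frame
    }
  }
  passages <- vector("list", h * w)
  if (length(pix_all)) {
    sp <- split(frm_all, pix_all)
    passages[as.integer(names(sp))] <- lapply(sp, sort)
  }
  idx0 <- which(maps[, , 1], arr.ind = TRUE)
  seeds0 <- cbind(row = idx0[, 1] - 1L, col = idx0[, 2] - 1L)
  structure(list(passages = passages, seeds0 = seeds0, n_frames = M,
                 dim = c(h, w), threshold_S = S,
                 n_events = length(pix_all)),
            class = "passage_map")
}

#' @export
print.passage_map <- function(x, ...) {
  cat(sprintf("passage_map: %d x %d px, M = %d, %d passage event(s), %d seed(s)\n",
              x$dim[1], x$dim[2], x$n_frames, x$n_events, nrow(x$seeds0)))
  invisible(x)
}

#' Dump a passage map as a data frame
#'
#' @param pmap A `passage_map`.
#' @return Data frame with 0-based columns `row`, `col`, `frame`, one row
#'   per passage event.
#' @export
passage_events <- function(pmap) {
  stopifnot(inherits(pmap, "passage_map"))
  h <- pmap$dim[1]
  nz <- which(!vapply(pmap$passages, is.null, logical(1)))
  if (!length(nz))
    return(data.frame(row = integer(0), col = integer(0), frame = integer(0)))
  rows <- integer(0); cols <- integer(0); frames <- integer(0)
  for (p in nz) {
    fr <- pmap$passages[[p]]
    rows <- c(rows, rep.int((p - 1L) %% h, length(fr)))
    cols <- c(cols, rep.int((p - 1L) %/% h, length(fr)))
    frames <- c(frames, fr)
  }
  df <- data.frame(row = rows, col = cols, frame = frames)
  df[order(df$row, df$col, df$frame), , drop = FALSE]
}
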