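# Phase A: reduce each frame to a binary map with exactly one saturated
# pixel per discerned target.  The chain is minimum filter -> global
# threshold (found iteratively from a user-counted region) -> mean filter
# -> local-maximum reduction, which marks one pixel per roughly circular
# target of at least min_blob_px pixels without any edge detection.

#' Segmentation parameters
#'
#' @param m_m Minimum-filter half-width in pixels; the mask is
#'   `(2*m_m+1) x (2*m_m+1)`.  Default 1 (a 3x3 mask).
#' @param m_b Mean/maximum-filter half-width.  Default 1; use 5 (11x11
#'   masks) for cell-scale targets such as lymphocytes.
#' @param threshold Global intensity threshold `T` in `[0, 1)`, or
#'   `"auto"` to search it on frame 0 (see [find_threshold()]), which then
#'   requires `roi` and `expected_count`.
#' @param roi Counting region for the automatic threshold, as
#'   `c(row0, col0, row1, col1)` (0-based, inclusive); `NULL` means the
#'   whole frame.
#' @param expected_count Number of targets the user counts inside `roi` on
#'   frame 0.
#' @param min_blob_px Minimum connected-component area (pixels) counted as
#'   a target.  Default 3.
#' @param single_peak_per_blob Keep only the strongest smoothed peak
#'   within each connected thresholded component.  For large uniform
#'   targets (cell-scale blobs, `m_b = 5`) shot noise on the flat top
#'   otherwise produces several near-equal local maxima per object,
#'   breaking the one-pixel-per-target output contract; a cell is a
#'   single connected component, so its strongest peak is the target
#'   position.  Leave `FALSE` (default) for point-like emitters, where
#'   one connected component may genuinely hold several close targets.
#' @return A `seg_params` list.
#' @export
seg_params <- function(m_m = 1L, m_b = 1L, threshold = "auto", roi = NULL,
                       expected_count = NULL, min_blob_px = 3L,
                       single_peak_per_blob = FALSE) {
  m_m <- as.integer(m_m); m_b <- as.integer(m_b)
  stopifnot(m_m >= 1L, m_b >= 1L, min_blob_px >= 1L)
  if (is.numeric(threshold)) stopifnot(threshold >= 0, threshold < 1)
  else if (!identical(threshold, "auto")) stop("threshold must be numeric or \"auto\"")
  structure(list(m_m = m_m, m_b = m_b, threshold = threshold, roi = roi,
                 expected_count = expected_count,
                 min_blob_px = as.integer(min_blob_px),
                 single_peak_per_blob = isTRUE(single_peak_per_blob)),
            class = "seg_params")
}

#' Minimum spatial filter
#'
#' Assigns to each pixel the minimum over its `(2*m_m+1) x (2*m_m+1)`
#' neighbourhood, suppressing high-frequency background components.  The
#' outer frame of `m_m` pixels is excluded from the analysis and set to 0.
#'
#' @param frame Numeric matrix, intensities in \[0, 1\].
#' @param m_m Half-width of the square mask.
#' @return Filtered matrix of the same shape.
#' @export
minimum_filter <- function(frame, m_m = 1L) {
  m_m <- as.integer(m_m)
  stopifnot(is.matrix(frame), m_m >= 1L)
  if (2L * m_m >= min(dim(frame)))
    stop("m_m = ", m_m, " leaves no interior for a ",
         nrow(frame), " x ", ncol(frame), " frame")
  out <- .sliding_min_cpp(frame, m_m)
  out[c(seq_len(m_m), nrow(out) - seq_len(m_m) + 1L), ] <- 0
  out[, c(seq_len(m_m), ncol(out) - seq_len(m_m) + 1L)] <- 0
  out
}

#' Apply a global intensity threshold
#'
#' Value-preserving: pixels at or above `T` keep their intensity, the rest
#' are set to 0, so the subsequent mean filter acts on graded intensities.
#' The same `T` is applied to the whole stack.
#'
#' @param frame Numeric matrix.
#' @param threshold `T` in `[0, 1)`.
#' @return Thresholded matrix.
#' @export
apply_threshold <- function(frame, threshold) {
  stopifnot(is.matrix(frame), threshold >= 0, threshold < 1)
  frame * (frame >= threshold)
}

#' Label 8-connected components of a binary mask
#'
#' @param mask Logical (or 0/1 numeric) matrix.
#' @return Integer matrix of labels `1..K` (0 = background), in scan order.
#' @export
label_components <- function(mask) {
  if (!is.logical(mask)) mask <- mask != 0
  .label_components_cpp(mask)
}

#' Find the segmentation threshold from a counted region
#'
#' Scans the threshold grid `0, step, 2*step, ...` (default step 1/1024
#' of the intensity range) and counts, at each level, the 8-connected
#' components of area at least `min_blob_px` inside `roi`.  Because noise
#' and graded background make the count fluctuate through the expected
#' value spuriously (single-step coincidences while the background
#' fragments), the returned `T` is the midpoint of the *longest* run of
#' consecutive grid levels attaining `expected_count` - the stable
#' plateau between the background and the dimmest target peak, taken at
#' its centre so the stack-wide threshold keeps margin against
#' frame-to-frame noise in both directions.  The frame should already be
#' minimum-filtered; counting happens after thresholding only.
#'
#' @param frame Minimum-filtered numeric matrix.
#' @param roi Counting rectangle `c(row0, col0, row1, col1)` (0-based,
#'   inclusive); `NULL` for the whole frame.
#' @param expected_count Target count the threshold must reproduce.
#' @param min_blob_px Minimum component area counted.
#' @param step Threshold grid step.
#' @return The threshold `T`.
#' @export
find_threshold <- function(frame, roi = NULL, expected_count,
                           min_blob_px = 3L, step = 1 / 1024) {
  stopifnot(is.matrix(frame), expected_count >= 1)
  sub <- if (is.null(roi)) frame else {
    stopifnot(length(roi) == 4, roi[1] <= roi[3], roi[2] <= roi[4])
    frame[(roi[1]:roi[3]) + 1L, (roi[2]:roi[4]) + 1L, drop = FALSE]
  }
  sc <- threshold_scan(frame, roi = roi, min_blob_px = min_blob_px,
                       step = step)
  grid <- sc$threshold; counts <- sc$count
  hit <- counts == expected_count
  if (!any(hit))
    stop("no threshold on the grid yields ", expected_count,
         " components; achievable counts range from ", min(counts),
         " to ", max(counts))
  runs <- rle(hit)
  ends <- cumsum(runs$lengths)
  ok <- which(runs$values)
  best <- ok[which.max(runs$lengths[ok])]      # longest run, earliest on ties
  first <- ends[best] - runs$lengths[best] + 1L
  grid[first + (runs$lengths[best] - 1L) %/% 2L]
}

#' Component counts over the whole threshold grid
#'
#' The raw material of [find_threshold()]: for every grid level, the
#' number of 8-connected components of area at least `min_blob_px` in
#' the thresholded region of interest.  Useful for choosing a reliable
#' target count - the counts attained over long stable runs of
#' consecutive levels are the ones a user can trust.
#'
#' @inheritParams find_threshold
#' @return Data frame with columns `threshold` and `count`.
#' @export
threshold_scan <- function(frame, roi = NULL, min_blob_px = 3L,
                           step = 1 / 1024) {
  stopifnot(is.matrix(frame))
  sub <- if (is.null(roi)) frame else {
    stopifnot(length(roi) == 4, roi[1] <= roi[3], roi[2] <= roi[4])
    frame[(roi[1]:roi[3]) + 1L, (roi[2]:roi[4]) + 1L, drop = FALSE]
  }
  grid <- seq(0, 1 - step, by = step)
  counts <- .component_counts_cpp(sub, grid, as.integer(min_blob_px))
  data.frame(threshold = grid, count = as.integer(counts))
}

#' Mean filter followed by local-maximum point reduction
#'
#' Smooths the thresholded frame with a `(2*m_b+1) x (2*m_b+1)` mean
#' filter, then marks the pixels whose smoothed value is positive and
#' equals the maximum over the same window.  Plateau ties within an
#' 8-connected equal-valued set keep only the lexicographically smallest
#' (row, col), so each target of size at least ~3 px yields one single
#' pixel.
#'
#' @param frame Thresholded numeric matrix.
#' @param m_b Half-width of the mean/maximum mask.
#' @param one_per_component Keep only the strongest marked pixel inside
#'   each connected component of the thresholded support (see
#'   [seg_params()]).
#' @return Logical matrix of marked target pixels.
#' @export
mean_max_reduce <- function(frame, m_b = 1L, one_per_component = FALSE) {
  m_b <- as.integer(m_b)
  stopifnot(is.matrix(frame), m_b >= 1L)
  s <- .sliding_mean_cpp(frame, m_b)
  mx <- .sliding_max_cpp(s, m_b)
  marked <- s > 0 & s == mx
  if (!any(marked)) return(marked)
  if (one_per_component) {
    # group by the smoothed support: s > 0 wherever the window touches
    # the thresholded blob, so every mark carries a nonzero label
    lab <- .label_components_cpp(s > 0)
    idx <- which(marked, arr.ind = TRUE)
    comp <- lab[marked]
    keep <- matrix(FALSE, nrow(frame), ncol(frame))
    for (k in unique(comp)) {
      pts <- idx[comp == k, , drop = FALSE]
      vals <- s[pts]
      best <- which(vals == max(vals))
      best <- best[order(pts[best, 1], pts[best, 2])][1]
      keep[pts[best, 1], pts[best, 2]] <- TRUE
    }
    marked <- keep
    if (!any(marked)) return(marked)
  }
  # adjacent marked pixels necessarily share the same smoothed value
  # (each lies in the other's window), so components of `marked` are the
  # plateau sets; keep the first pixel in column-major scan order, which
  # is the lexicographically smallest (row, col) after transposition care
  lab <- .label_components_cpp(marked)
  keep <- matrix(FALSE, nrow(frame), ncol(frame))
  idx <- which(marked, arr.ind = TRUE)
  lab_of <- lab[marked]
  for (k in seq_len(max(lab_of))) {
    pts <- idx[lab_of == k, , drop = FALSE]
    best <- order(pts[, 1], pts[, 2])[1]          # smallest (row, col)
    keep[pts[best, 1], pts[best, 2]] <- TRUE
  }
  keep
}

#' Construct a detection stack
#'
#' @param maps Logical array `height x width x n_frames`; `TRUE` marks a
#'   segmented target position (single pixel per target).
#' @param border_margin Width of the outer frame excluded from analysis.
#' @param threshold Threshold `T` actually applied (recorded for
#'   provenance).
#' @param params The [seg_params()] used, if any.
#' @return A `detection_stack` object.
#' @export
detection_stack <- function(maps, border_margin = 0L, threshold = NA_real_,
                            params = NULL) {
  if (is.matrix(maps)) maps <- array(maps, dim = c(dim(maps), 1))
  if (!is.logical(maps)) maps <- maps != 0
  structure(list(maps = maps, n_frames = dim(maps)[3],
                 height = dim(maps)[1], width = dim(maps)[2],
                 border_margin = as.integer(border_margin),
                 threshold = threshold, params = params),
            class = "detection_stack")
}

#' @export
print.detection_stack <- function(x, ...) {
  cat(sprintf("detection_stack: %d frame(s), %d x %d px, %d marks, T = %.4g\n",
              x$n_frames, x$height, x$width, sum(x$maps), x$threshold))
  invisible(x)
}

#' Segment a full image stack (phase A)
#'
#' Applies, per frame, the four-filter chain: minimum filter, global
#' threshold (shared by the whole stack; found on frame 0 when
#' `threshold = "auto"`), mean filter and local-maximum reduction.  Marks
#' falling within `border_margin = m_m + m_b` of the image edge are
#' removed.
#'
#' @param stack An [image_stack()].
#' @param params A [seg_params()].
#' @return A [detection_stack()].
#' @export
segment_stack <- function(stack, params = seg_params()) {
  stopifnot(inherits(stack, "image_stack"), inherits(params, "seg_params"))
  m_m <- params$m_m; m_b <- params$m_b
  f0 <- minimum_filter(stack$frames[, , 1], m_m)
  T <- if (identical(params$threshold, "auto")) {
    if (is.null(params$expected_count))
      stop("threshold = \"auto\" requires expected_count (and usually roi)")
    find_threshold(f0, roi = params$roi,
                   expected_count = params$expected_count,
                   min_blob_px = params$min_blob_px)
  } else params$threshold
  margin <- m_m + m_b
  maps <- array(FALSE, dim = dim(stack$frames))
  for (j in seq_len(stack$n_frames)) {
    fr <- if (j == 1) f0 else minimum_filter(stack$frames[, , j], m_m)
    marks <- mean_max_reduce(apply_threshold(fr, T), m_b,
                             one_per_component = params$single_peak_per_blob)
    maps[, , j] <- marks
  }
  if (margin > 0) {
    maps[c(seq_len(margin), stack$height - seq_len(margin) + 1L), , ] <- FALSE
    maps[, c(seq_len(margin), stack$width - seq_len(margin) + 1L), ] <- FALSE
  }
  detection_stack(maps, border_margin = margin, threshold = T, params = params)
}

#' Detected positions on one frame
#'
#' @param det A [detection_stack()].
#' @param frame 0-based frame index.
#' @return Two-column matrix of 0-based `(row, col)` marks.
#' @export
detections_at <- function(det, frame = 0L) {
  stopifnot(inherits(det, "detection_stack"),
            frame >= 0, frame < det$n_frames)
  idx <- which(det$maps[, , frame + 1L], arr.ind = TRUE)
  cbind(row = idx[, 1] - 1L, col = idx[, 2] - 1L)
}
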