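# ImageStack: the raw/normalized time series I_j(h, k), j = 0..M-1.
#
# Coordinate convention used throughout the package: 0-based (row, col)
# with row 0 at the image top; frame indices are 0-based.  Physical
# micrometre coordinates appear only at export and statistics time
# (x_um = col * pixel_size_um, y_um = row * pixel_size_um).

#' Construct an image stack
#'
#' @param frames Numeric array `height x width x n_frames` with intensities
#'   in \[0, 1\] (use [read_stack()] to load and normalize files).
#' @param pixel_size_um Physical pixel size in micrometres.
#' @param frame_interval_s Time between consecutive frames in seconds.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, pixel_size_um = 1, frame_interval_s = 1) {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1))
  stopifnot(length(dim(frames)) == 3, pixel_size_um > 0, frame_interval_s > 0)
  if (any(frames < 0 | frames > 1))
    stop("image_stack intensities must lie in [0, 1]; normalize first")
  structure(
    list(frames = frames,
         n_frames = dim(frames)[3],
         height = dim(frames)[1], width = dim(frames)[2],
         pixel_size_um = pixel_size_um,
         frame_interval_s = frame_interval_s),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("image_stack: %d frame(s), %d x %d px, %.4g um/px, %.4g s/frame\n",
              x$n_frames, x$height, x$width, x$pixel_size_um, x$frame_interval_s))
  invisible(x)
}

.normalize_frames <- function(frames, bits, sample_format) {
  if (sample_format == "uint") {
    frames / (2^bits - 1)
  } else {
    rng <- range(frames)
    if (diff(rng) == 0) return(array(0, dim = dim(frames)))
    # min-max per stack (not per frame) so one threshold T is meaningful
    # across all frames
    (frames - rng[1]) / diff(rng)
  }
}

#' Load an image stack from TIFF
#'
#' Reads a multi-page TIFF, or a directory of same-shape single-page TIFFs
#' ordered by lexicographic filename.  Integer samples are rescaled to
#' \[0, 1\] by the type maximum (255 or 65535); float samples are min-max
#' normalized per stack.
#'
#' @param path A TIFF file or a directory containing `.tif`/`.tiff` files.
#' @inheritParams image_stack
#' @return An [image_stack()].
#' @export
read_stack <- function(path, pixel_size_um = 1, frame_interval_s = 1) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) < 1) stop("no TIFF files found in directory: ", path)
    pages <- lapply(files, read_tiff_gray)
    dims <- unique(lapply(pages, function(p) dim(p$frames)[1:2]))
    if (length(dims) != 1) stop("inconsistent frame shapes across files in ", path)
    bits <- pages[[1]]$bits; fmt <- pages[[1]]$sample_format
    frames <- array(NA_real_,
                    dim = c(dims[[1]], sum(vapply(pages, function(p) dim(p$frames)[3], 1))))
    k <- 0L
    for (p in pages) for (j in seq_len(dim(p$frames)[3])) {
      k <- k + 1L; frames[, , k] <- p$frames[, , j]
    }
  } else {
    tf <- read_tiff_gray(path)
    frames <- tf$frames; bits <- tf$bits; fmt <- tf$sample_format
  }
  image_stack(.normalize_frames(frames, bits, fmt),
              pixel_size_um = pixel_size_um, frame_interval_s = frame_interval_s)
}

#' Write an image stack to a multi-page TIFF
#'
#' @param stack An [image_stack()].
#' @param path Output path.
#' @param bits `8`, `16` (intensities rescaled to the integer range) or
#'   `"float32"` (written verbatim).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits = 16) {
  stopifnot(inherits(stack, "image_stack"))
  fr <- stack$frames
  if (!identical(bits, "float32")) fr <- round(fr * (2^as.integer(bits) - 1))
  write_tiff_gray(fr, path, bits = bits)
}

#' Write a trajectory set to CSV
#'
#' One row per trajectory sample, sorted by (target_id, frame), with both
#' pixel and physical coordinates:
#' `target_id, frame, row, col, x_um, y_um` where
#' `x_um = col * pixel_size_um` and `y_um = row * pixel_size_um`.
#'
#' @param trajs A [trajectory_set()].
#' @param path Output CSV path.
#' @param pixel_size_um Pixel size used for the physical columns; defaults
#'   to the value recorded in `trajs`, else 1.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajs, path, pixel_size_um = NULL) {
  stopifnot(inherits(trajs, "trajectory_set"))
  if (is.null(pixel_size_um))
    pixel_size_um <- if (!is.null(trajs$pixel_size_um)) trajs$pixel_size_um else 1
  df <- as.data.frame(trajs)
  df$x_um <- df$col * pixel_size_um
  df$y_um <- df$row * pixel_size_um
  df <- df[order(df$target_id, df$frame),
           c("target_id", "frame", "row", "col", "x_um", "y_um")]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory set from CSV
#'
#' Inverse of [write_trajectories()].
#'
#' @param path CSV path with columns `target_id, frame, row, col`.
#' @return A [trajectory_set()].
#' @export
read_trajectories <- function(path) {
  df <- read.csv(path)
  need <- c("target_id", "frame", "row", "col")
  if (!all(need %in% names(df)))
    stop("trajectory CSV must contain columns: ", paste(need, collapse = ", "))
  trajs <- lapply(split(df, df$target_id), function(d) {
    d <- d[order(d$frame), ]
    trajectory(d$target_id[1],
               cbind(frame = d$frame, row = d$row, col = d$col))
  })
  ids <- vapply(trajs, function(t) t$target_id, numeric(1))
  trajectory_set(trajs[order(ids)])
}
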