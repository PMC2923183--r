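# Phases D and G: all trajectories on one 2D image with occupancy time
# coded by color (dark-to-light green by default, or jet), magenta seed
# pixels for frame-0 targets, per-target numeric labels colored red to
# blue by start time, and per-frame overlay export for movie mounting.

#' Rendering specification for trajectory images
#'
#' @param colormap `"green-levels"` (dark to light green, monotone in
#'   time) or `"jet"`.
#' @param show_seed_pixels Paint frame-0 target positions magenta.
#' @param show_labels Draw each target id at its first sample, colored
#'   from red (early start) to blue (late start).
#' @param background `"first-frame"` uses frame 0 as grayscale backdrop;
#'   `"black"` starts from zeros.
#' @return A `render_spec` list.
#' @export
render_spec <- function(colormap = c("green-levels", "jet"),
                        show_seed_pixels = TRUE, show_labels = TRUE,
                        background = c("first-frame", "black")) {
  structure(list(colormap = match.arg(colormap),
                 show_seed_pixels = show_seed_pixels,
                 show_labels = show_labels,
                 background = match.arg(background)),
            class = "render_spec")
}

# time fraction in [0,1] -> RGB row vector
.time_color <- function(frac, colormap) {
  if (colormap == "green-levels") {
    cbind(0, 0.25 + 0.75 * frac, 0)
  } else {                      # piecewise-linear jet approximation
    r <- pmin(pmax(1.5 - abs(4 * frac - 3), 0), 1)
    g <- pmin(pmax(1.5 - abs(4 * frac - 2), 0), 1)
    b <- pmin(pmax(1.5 - abs(4 * frac - 1), 0), 1)
    cbind(r, g, b)
  }
}

# 3x5 bitmap digit font, columns are glyph rows (1 = on)
.digit_font <- local({
  glyphs <- c(
    "111101101101111", "010110010010111", "111001111100111",
    "111001111001111", "101101111001001", "111100111001111",
    "111100111101111", "111001001001001", "111101111101111",
    "111101111001111")
  lapply(glyphs, function(g)
    matrix(as.integer(strsplit(g, "")[[1]]) == 1L, nrow = 5, byrow = TRUE))
})

.draw_label <- function(img, text, row, col, rgb, occupied) {
  digits <- as.integer(strsplit(text, "")[[1]])
  wid <- 4L * length(digits) - 1L
  h <- dim(img)[1]; w <- dim(img)[2]
  # shift diagonally by +1 px until the label box is free
  for (shift in 0:16) {
    r0 <- row + shift; c0 <- col + shift
    if (r0 + 4 >= h || c0 + wid - 1 >= w) break
    box <- occupied[(r0:(r0 + 4)) + 1L, (c0:(c0 + wid - 1)) + 1L]
    if (!any(box)) break
  }
  if (r0 + 4 >= h || c0 + wid - 1 >= w) return(list(img = img, occupied = occupied))
  for (d in seq_along(digits)) {
    glyph <- .digit_font[[digits[d] + 1L]]
    rr <- r0 + 0:4; cc <- c0 + (d - 1L) * 4L + 0:2
    for (gi in 1:5) for (gj in 1:3) if (glyph[gi, gj]) {
      img[rr[gi] + 1L, cc[gj] + 1L, ] <- rgb
    }
  }
  occupied[(r0:(r0 + 4)) + 1L, (c0:(c0 + wid - 1)) + 1L] <- TRUE
  list(img = img, occupied = occupied)
}

.background_rgb <- function(stack, spec) {
  h <- stack$height; w <- stack$width
  img <- array(0, dim = c(h, w, 3))
  if (spec$background == "first-frame")
    img[] <- rep(stack$frames[, , 1], 3)
  img
}

#' Render all trajectories on a single time-color-coded image (phase D)
#'
#' Every trajectory sample paints its pixel with the colormap evaluated
#' at `t / (M - 1)`; later passage times overwrite earlier ones at
#' shared pixels.  Frame-0 seed positions are painted magenta and each
#' trajectory is labeled by its target id at its first sample, the label
#' color running red to blue with start time.
#'
#' @param trajs A [trajectory_set()].
#' @param stack The source [image_stack()] (backdrop and dimensions).
#' @param spec A [render_spec()].
#' @return RGB array `height x width x 3` in \[0, 1\].
#' @export
render_trajectory_image <- function(trajs, stack, spec = render_spec()) {
  stopifnot(inherits(trajs, "trajectory_set"), inherits(stack, "image_stack"))
  img <- .background_rgb(stack, spec)
  M <- stack$n_frames
  df <- as.data.frame(trajs)
  if (nrow(df)) {
    df <- df[order(df$frame), ]                 # later times overwrite
    frac <- df$frame / max(M - 1, 1)
    cols <- .time_color(frac, spec$colormap)
    for (i in seq_len(nrow(df)))
      img[round(df$row[i]) + 1L, round(df$col[i]) + 1L, ] <- cols[i, ]
  }
  if (spec$show_seed_pixels && nrow(df)) {
    seeds <- df[df$frame == 0, , drop = FALSE]
    for (i in seq_len(nrow(seeds)))
      img[round(seeds$row[i]) + 1L, round(seeds$col[i]) + 1L, ] <- c(1, 0, 1)
  }
  if (spec$show_labels && length(trajs$trajectories)) {
    occupied <- matrix(FALSE, stack$height, stack$width)
    for (tr in trajs$trajectories) {
      frac0 <- tr$start_frame / max(M - 1, 1)
      rgb <- c(1 - frac0, 0, frac0)
      res <- .draw_label(img, as.character(tr$target_id),
                         round(tr$samples[1, "row"]),
                         round(tr$samples[1, "col"]), rgb, occupied)
      img <- res$img; occupied <- res$occupied
    }
  }
  img
}

#' Render per-frame overlays of one trajectory (phase G)
#'
#' Frame `j` shows the original image with the cumulative trace of the
#' trajectory's samples up to `j`, painted with the time colormap.
#'
#' @param stack An [image_stack()].
#' @param traj A [trajectory()].
#' @param spec A [render_spec()].
#' @return List of RGB arrays, one per stack frame.
#' @export
render_overlay_frames <- function(stack, traj, spec = render_spec()) {
  stopifnot(inherits(stack, "image_stack"), inherits(traj, "trajectory"))
  M <- stack$n_frames
  s <- traj$samples
  if (any(s[, "frame"] >= M)) stop("trajectory frames exceed stack range")
  cols <- .time_color(s[, "frame"] / max(M - 1, 1), spec$colormap)
  lapply(seq_len(M) - 1L, function(j) {
    img <- array(rep(stack$frames[, , j + 1L], 3),
                 dim = c(stack$height, stack$width, 3))
    vis <- which(s[, "frame"] <= j)
    for (i in vis)
      img[round(s[i, "row"]) + 1L, round(s[i, "col"]) + 1L, ] <- cols[i, ]
    img
  })
}

#' Write an RGB (or grayscale) image as PNG
#'
#' Minimal self-contained 8-bit PNG writer (zlib via [memCompress()]),
#' so figures can be exported without external imaging libraries.
#'
#' @param img Numeric array `height x width x 3` or matrix, values in
#'   \[0, 1\].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_png <- function(img, path) {
  if (is.matrix(img)) img <- array(rep(img, 3), dim = c(dim(img), 3))
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  h <- dim(img)[1]; w <- dim(img)[2]
  px <- round(pmin(pmax(img, 0), 1) * 255)
  # scanlines: filter byte 0 + RGBRGB... per row
  bytes <- raw(h * (1L + 3L * w))
  for (i in seq_len(h)) {
    off <- (i - 1L) * (1L + 3L * w) + 1L
    rowdat <- as.vector(rbind(px[i, , 1], px[i, , 2], px[i, , 3]))
    bytes[(off + 1L):(off + 3L * w)] <- as.raw(rowdat)
  }
  idat <- memCompress(bytes, "gzip")          # zlib stream (0x78 ...)

  crc_table <- local({
    tab <- integer(256)
    for (n in 0:255) {
      c <- n
      for (k in 1:8)
        c <- if (bitwAnd(c, 1L)) bitwXor(-306674912L, bitwShiftR(bitwAnd(c, -2L), 1))
             else bitwShiftR(bitwAnd(c, -2L), 1)
      tab[n + 1] <- c
    }
    tab
  })
  crc32 <- function(data) {
    c <- -1L
    for (b in as.integer(data))
      c <- bitwXor(crc_table[bitwAnd(bitwXor(c, b), 255L) + 1L],
                   bitwShiftR(bitwAnd(c, -256L), 8))
    bitwXor(c, -1L)
  }
  u32 <- function(x) {
    x <- as.numeric(x) %% 2^32
    as.raw(c(x %/% 2^24, (x %/% 2^16) %% 256, (x %/% 256) %% 256, x %% 256))
  }
  chunk <- function(type, data) {
    payload <- c(charToRaw(type), data)
    c(u32(length(data)), payload, u32(crc32(payload)))
  }
  ihdr <- c(u32(w), u32(h), as.raw(c(8, 2, 0, 0, 0)))  # 8-bit RGB
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           chunk("IHDR", ihdr), chunk("IDAT", idat),
           chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}
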