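# Minimal baseline TIFF support: uncompressed, single-sample (grayscale),
# 8/16-bit unsigned or 32-bit float, single- or multi-page, either byte
# order on read, little-endian on write.  This covers the "multi-tiff"
# stacks microscopy acquisition software commonly exports, and nothing
# more; compressed, tiled, palette or multi-sample files are rejected.

.tiff_type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `11` = 4L, `12` = 8L)

.rd_uint <- function(raw, off, size, endian) {
  b <- as.integer(raw[(off + 1):(off + size)])
  if (endian == "big") b <- rev(b)
  sum(b * 256^(seq_len(size) - 1))
}

.rd_uint_vec <- function(raw, off, size, n, endian) {
  vapply(seq_len(n) - 1L, function(i) .rd_uint(raw, off + i * size, size, endian), numeric(1))
}

#' Read an uncompressed grayscale TIFF file
#'
#' Low-level reader returning raw (un-normalized) pixel data.  Most users
#' want [read_stack()], which also attaches calibration metadata and
#' normalizes intensities to \[0, 1\].
#'
#' @param path Path to a single- or multi-page TIFF file.
#' @return A list with `frames` (numeric array `height x width x n_frames`,
#'   raw sample values), `bits` (8, 16 or 32) and `sample_format`
#'   (`"uint"` or `"float"`).
#' @seealso [write_tiff_gray()], [read_stack()]
#' @export
read_tiff_gray <- function(path) {
  if (!file.exists(path)) stop("TIFF file not found: ", path)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  magic <- rawToChar(raw[1:2])
  endian <- switch(magic, II = "little", MM = "big",
                   stop("not a TIFF file (bad byte-order mark): ", path))
  if (.rd_uint(raw, 2, 2, endian) != 42) stop("not a TIFF file (bad magic): ", path)

  pages <- list()
  ifd_off <- .rd_uint(raw, 4, 4, endian)
  while (ifd_off != 0) {
    n_ent <- .rd_uint(raw, ifd_off, 2, endian)
    tags <- list()
    for (e in seq_len(n_ent)) {
      base <- ifd_off + 2 + (e - 1) * 12
      tag <- .rd_uint(raw, base, 2, endian)
      typ <- .rd_uint(raw, base + 2, 2, endian)
      cnt <- .rd_uint(raw, base + 4, 4, endian)
      tsz <- .tiff_type_size[as.character(typ)]
      if (is.na(tsz)) next
      vals <- if (tsz * cnt <= 4) {
        .rd_uint_vec(raw, base + 8, tsz, cnt, endian)
      } else {
        .rd_uint_vec(raw, .rd_uint(raw, base + 8, 4, endian), tsz, cnt, endian)
      }
      tags[[as.character(tag)]] <- vals
    }
    pages[[length(pages) + 1L]] <- tags
    ifd_off <- .rd_uint(raw, ifd_off + 2 + n_ent * 12, 4, endian)
  }
  if (length(pages) == 0) stop("TIFF file contains no images: ", path)

  get1 <- function(tags, tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) default else v[1]
  }
  frames <- NULL
  for (p in seq_along(pages)) {
    tg <- pages[[p]]
    w <- get1(tg, 256); h <- get1(tg, 257)
    if (is.null(w) || is.null(h)) stop("TIFF page ", p, " lacks dimensions")
    if (get1(tg, 259, 1) != 1) stop("compressed TIFF not supported: ", path)
    if (get1(tg, 277, 1) != 1) stop("multi-sample TIFF not supported: ", path)
    bits <- get1(tg, 258, 8)
    fmt <- get1(tg, 339, 1)
    if (!(bits %in% c(8, 16) && fmt == 1) && !(bits == 32 && fmt == 3))
      stop("unsupported TIFF sample type (", bits, "-bit, format ", fmt, ")")
    offs <- tg[["273"]]; cnts <- tg[["279"]]
    if (is.null(offs)) stop("TIFF page ", p, " lacks strip offsets")
    bstr <- raw(0)
    for (s in seq_along(offs))
      bstr <- c(bstr, raw[(offs[s] + 1):(offs[s] + cnts[s])])
    vals <- if (bits == 32) {
      readBin(bstr, "double", n = w * h, size = 4, endian = endian)
    } else {
      readBin(bstr, "integer", n = w * h, size = bits / 8,
              signed = FALSE, endian = endian)
    }
    fr <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
    if (is.null(frames)) {
      frames <- array(NA_real_, dim = c(h, w, length(pages)))
    } else if (!all(dim(frames)[1:2] == c(h, w))) {
      stop("inconsistent frame shapes across TIFF pages")
    }
    frames[, , p] <- fr
  }
  bits_out <- get1(pages[[1]], 258, 8)
  list(frames = frames, bits = bits_out,
       sample_format = if (bits_out == 32) "float" else "uint")
}

#' Write an uncompressed grayscale TIFF file
#'
#' @param frames Numeric array `height x width x n_frames` (or a matrix for
#'   a single page).  For integer `bits`, values must already lie in
#'   `0 .. 2^bits - 1`; for `bits = "float32"` values are written verbatim.
#' @param path Output file path.
#' @param bits `8`, `16` or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_tiff_gray <- function(frames, path, bits = 16) {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1))
  stopifnot(length(dim(frames)) == 3)
  h <- dim(frames)[1]; w <- dim(frames)[2]; m <- dim(frames)[3]
  is_float <- identical(bits, "float32")
  if (!is_float) {
    bits <- as.integer(bits)
    stopifnot(bits %in% c(8L, 16L))
    if (any(frames < 0 | frames > 2^bits - 1))
      stop("integer TIFF values out of range for ", bits, "-bit output")
  }
  bytes_px <- if (is_float) 4L else bits / 8L
  data_bytes <- h * w * bytes_px
  n_ent <- 10L
  ifd_bytes <- 2L + n_ent * 12L + 4L

  con <- file(path, "wb")
  on.exit(close(con))
  wr16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  wr32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  entry <- function(tag, type, count, value) {
    wr16(tag); wr16(type); wr32(count)
    if (type == 3) { wr16(value); wr16(0) } else wr32(value)
  }

  writeBin(charToRaw("II"), con); wr16(42L)
  first_ifd <- 8L + data_bytes
  wr32(first_ifd)
  for (p in seq_len(m)) {
    # page layout: [data][IFD], pages appended in sequence
    vals <- as.vector(t(frames[, , p]))           # TIFF is row-major
    if (is_float) {
      writeBin(vals, con, size = 4, endian = "little")
    } else {
      writeBin(as.integer(round(vals)), con, size = bytes_px, endian = "little")
    }
    page_start <- 8L + (p - 1L) * (data_bytes + ifd_bytes)
    wr16(n_ent)
    entry(256, 4, 1, w)                            # ImageWidth
    entry(257, 4, 1, h)                            # ImageLength
    entry(258, 3, 1, if (is_float) 32L else bits)  # BitsPerSample
    entry(259, 3, 1, 1L)                           # Compression: none
    entry(262, 3, 1, 1L)                           # Photometric: min-is-black
    entry(273, 4, 1, page_start)                   # StripOffsets
    entry(277, 3, 1, 1L)                           # SamplesPerPixel
    entry(278, 4, 1, h)                            # RowsPerStrip
    entry(279, 4, 1, data_bytes)                   # StripByteCounts
    entry(339, 3, 1, if (is_float) 3L else 1L)     # SampleFormat
    next_ifd <- if (p < m) page_start + data_bytes + ifd_bytes + data_bytes else 0L
    wr32(next_ifd)
  }
  invisible(path)
}
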