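# Minimal baseline TIFF codec: little-endian, grayscale, uncompressed,
# multi-page; 8/16-bit unsigned integer and 32/64-bit IEEE float samples.
# Implemented in base R because the target environment has no TIFF
# bindings; covers exactly what the instrument files and derived maps
# need (single-sample strips, no tiles, no compression, no color).

TIFF_TAGS <- c(ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
               Compression = 259L, Photometric = 262L, StripOffsets = 273L,
               SamplesPerPixel = 277L, RowsPerStrip = 278L,
               StripByteCounts = 279L, SampleFormat = 339L)

# -- writing ------------------------------------------------------------

write_u16 <- function(con, v) {
  v <- as.integer(round(v))
  v[v > 32767L] <- v[v > 32767L] - 65536L  # two's-complement reinterpret
  writeBin(v, con, size = 2L, endian = "little")
}
write_u32 <- function(con, v) {
  v <- as.numeric(v)
  v[v > 2147483647] <- v[v > 2147483647] - 4294967296
  writeBin(as.integer(v), con, size = 4L, endian = "little")
}

# One IFD entry: tag, type (3 = SHORT, 4 = LONG), count 1, value.
tiff_entry <- function(con, tag, type, value) {
  write_u16(con, tag)
  write_u16(con, type)
  write_u32(con, 1L)
  if (type == 3L) { write_u16(con, value); write_u16(con, 0L) }
  else write_u32(con, value)
}

#' Write a grayscale (multi-page) TIFF
#'
#' Writes a matrix or 3-D array as an uncompressed little-endian grayscale
#' TIFF, one page per frame.  `sample_format = "uint16"` stores rounded
#' 16-bit counts (raw camera frames); `"float32"` stores IEEE floats
#' (derived contrast / correlation-time maps, `NaN` encoding invalid
#' pixels).
#'
#' @param x numeric matrix or `rows x cols x frames` array.
#' @param path output file path.
#' @param sample_format `"uint16"` or `"float32"`.
#' @return `path`, invisibly.
#' @seealso [read_tiff()]
#' @export
write_tiff <- function(x, path, sample_format = c("uint16", "float32")) {
  sample_format <- match.arg(sample_format)
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L)
    stop_param("'x' must be a matrix or 3-D array")
  if (sample_format == "uint16" &&
      any(x < 0 | x > 65535, na.rm = TRUE))
    stop_param("uint16 TIFF requires values in [0, 65535]")
  d <- dim(x); h <- d[1L]; w <- d[2L]; n <- d[3L]
  bps <- if (sample_format == "uint16") 16L else 32L
  fmt <- if (sample_format == "uint16") 1L else 3L
  bytes_pp <- bps %/% 8L
  strip_bytes <- h * w * bytes_pp
  n_entries <- 10L
  ifd_bytes <- 2L + n_entries * 12L + 4L

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  write_u16(con, 42L)
  # layout: header (8) then per page [pixel data][IFD]
  first_ifd <- 8L + strip_bytes
  write_u32(con, first_ifd)
  offset <- 8L
  for (p in seq_len(n)) {
    frame <- t(x[, , p])  # TIFF stores row-major (rows of the image)
    if (sample_format == "uint16") write_u16(con, as.vector(frame))
    else writeBin(as.vector(frame), con, size = 4L, endian = "little")
    ifd_off <- offset + strip_bytes
    write_u16(con, n_entries)
    tiff_entry(con, TIFF_TAGS[["ImageWidth"]], 4L, w)
    tiff_entry(con, TIFF_TAGS[["ImageLength"]], 4L, h)
    tiff_entry(con, TIFF_TAGS[["BitsPerSample"]], 3L, bps)
    tiff_entry(con, TIFF_TAGS[["Compression"]], 3L, 1L)
    tiff_entry(con, TIFF_TAGS[["Photometric"]], 3L, 1L)
    tiff_entry(con, TIFF_TAGS[["StripOffsets"]], 4L, offset)
    tiff_entry(con, TIFF_TAGS[["SamplesPerPixel"]], 3L, 1L)
    tiff_entry(con, TIFF_TAGS[["RowsPerStrip"]], 4L, h)
    tiff_entry(con, TIFF_TAGS[["StripByteCounts"]], 4L, strip_bytes)
    tiff_entry(con, TIFF_TAGS[["SampleFormat"]], 3L, fmt)
    next_ifd <- if (p < n) ifd_off + ifd_bytes + strip_bytes else 0L
    write_u32(con, next_ifd)
    offset <- ifd_off + ifd_bytes
  }
  invisible(path)
}

# -- reading ------------------------------------------------------------

read_u16 <- function(raw, pos, endian) {
  readBin(raw[pos:(pos + 1L)], "integer", size = 2L, signed = FALSE,
          endian = endian)
}
read_u32 <- function(raw, pos, endian) {
  v <- readBin(raw[pos:(pos + 3L)], "integer", size = 4L, endian = endian)
  if (v < 0) v + 4294967296 else v
}

#' Read a grayscale (multi-page) TIFF
#'
#' Reads uncompressed grayscale TIFF files (both byte orders; 8/16-bit
#' unsigned and 32/64-bit float samples; strip-organized).  RGB,
#' compressed or tiled files raise format errors with explicit messages.
#'
#' @param path TIFF file path.
#' @return Numeric `rows x cols x frames` array.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  order <- rawToChar(raw[1:2])
  endian <- switch(order, II = "little", MM = "big",
                   stop_param("not a TIFF file: bad byte-order mark"))
  if (read_u16(raw, 3L, endian) != 42L)
    stop_param("not a TIFF file: bad magic number")
  ifd <- read_u32(raw, 5L, endian)
  frames <- list()
  while (ifd != 0L) {
    n <- read_u16(raw, ifd + 1L, endian)
    tag_val <- function(tag, default = NULL) {
      for (i in seq_len(n)) {
        e <- ifd + 2L + (i - 1L) * 12L
        if (read_u16(raw, e + 1L, endian) == tag) {
          type <- read_u16(raw, e + 3L, endian)
          count <- read_u32(raw, e + 5L, endian)
          if (count != 1L) {
            # multi-strip offsets/counts: stored out-of-line as LONGs
            off <- read_u32(raw, e + 9L, endian)
            sz <- if (type == 3L) 2L else 4L
            rd <- if (type == 3L) read_u16 else read_u32
            return(vapply(seq_len(count) - 1L,
                          function(k) rd(raw, off + k * sz + 1L, endian),
                          numeric(1)))
          }
          return(if (type == 3L) read_u16(raw, e + 9L, endian)
                 else read_u32(raw, e + 9L, endian))
        }
      }
      default
    }
    w <- tag_val(TIFF_TAGS[["ImageWidth"]])
    h <- tag_val(TIFF_TAGS[["ImageLength"]])
    if (is.null(w) || is.null(h)) stop_param("TIFF page missing dimensions")
    if (tag_val(TIFF_TAGS[["Compression"]], 1L) != 1L)
      stop_param("compressed TIFF not supported (uncompressed grayscale only)")
    if (tag_val(TIFF_TAGS[["SamplesPerPixel"]], 1L) != 1L)
      stop_param("RGB/multi-sample TIFF not supported (grayscale only)")
    bps <- tag_val(TIFF_TAGS[["BitsPerSample"]], 1L)
    fmt <- tag_val(TIFF_TAGS[["SampleFormat"]], 1L)
    offs <- tag_val(TIFF_TAGS[["StripOffsets"]])
    cnts <- tag_val(TIFF_TAGS[["StripByteCounts"]], h * w * bps / 8)
    if (is.null(offs)) stop_param("TIFF page missing strip offsets")
    data_raw <- do.call(c, lapply(seq_along(offs), function(i)
      raw[(offs[i] + 1L):(offs[i] + cnts[i])]))
    npx <- h * w
    px <- if (fmt == 3L) {
      if (!bps %in% c(32L, 64L)) stop_param("unsupported float bit depth")
      readBin(data_raw, "double", n = npx, size = bps %/% 8L, endian = endian)
    } else if (fmt %in% c(1L, 4L)) {
      if (bps == 8L) as.numeric(readBin(data_raw, "integer", n = npx,
                                        size = 1L, signed = FALSE))
      else if (bps == 16L) as.numeric(readBin(data_raw, "integer", n = npx,
                                              size = 2L, signed = FALSE,
                                              endian = endian))
      else stop_param("unsupported integer bit depth")
    } else stop_param("unsupported TIFF sample format")
    frames[[length(frames) + 1L]] <- t(matrix(px, nrow = w, ncol = h))
    ifd <- read_u32(raw, ifd + 2L + n * 12L + 1L, endian)
  }
  if (length(frames) == 0L) stop_param("TIFF contains no pages")
  d1 <- dim(frames[[1L]])
  out <- array(NA_real_, c(d1, length(frames)))
  for (i in seq_along(frames)) out[, , i] <- frames[[i]]
  out
}
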