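# Minimal GeoTIFF codec: single-band, uncompressed, strip-organised rasters
# with ModelPixelScale/ModelTiepoint georeferencing and the GDAL nodata tag.
# Writing always produces little-endian IEEE float (32- or 64-bit); reading
# additionally accepts integer sample formats and big-endian files.

TIFF_TYPE_SIZE <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L,
                    `6` = 1L, `7` = 1L, `8` = 2L, `9` = 4L, `10` = 8L,
                    `11` = 4L, `12` = 8L)

.rd_int <- function(raw, off, n, size, signed, endian) {
  # readBin only honours `signed` for sizes 1 and 2; 4-byte values are
  # always read signed (offsets < 2^31, which this codec never exceeds)
  readBin(raw[(off + 1):(off + n * size)], what = "integer", n = n,
          size = size, signed = if (size >= 4) TRUE else signed,
          endian = endian)
}

.rd_dbl <- function(raw, off, n, size, endian) {
  readBin(raw[(off + 1):(off + n * size)], what = "double", n = n,
          size = size, endian = endian)
}

# Returns list(tag = int, values = numeric/character) for one 12-byte entry
.read_ifd_entry <- function(raw, off, endian) {
  tag   <- .rd_int(raw, off, 1L, 2L, signed = FALSE, endian = endian)
  type  <- .rd_int(raw, off + 2L, 1L, 2L, signed = FALSE, endian = endian)
  count <- .rd_int(raw, off + 4L, 1L, 4L, signed = FALSE, endian = endian)
  size  <- TIFF_TYPE_SIZE[as.character(type)]
  if (is.na(size)) return(list(tag = tag, values = NULL))
  nbytes <- size * count
  voff <- if (nbytes <= 4L) off + 8L else
    .rd_int(raw, off + 8L, 1L, 4L, signed = FALSE, endian = endian)
  values <- switch(as.character(type),
    `1` = .rd_int(raw, voff, count, 1L, FALSE, endian),
    `2` = rawToChar(raw[(voff + 1):(voff + count)]),
    `3` = .rd_int(raw, voff, count, 2L, FALSE, endian),
    `4` = .rd_int(raw, voff, count, 4L, FALSE, endian),
    `6` = .rd_int(raw, voff, count, 1L, TRUE, endian),
    `8` = .rd_int(raw, voff, count, 2L, TRUE, endian),
    `9` = .rd_int(raw, voff, count, 4L, TRUE, endian),
    `11` = .rd_dbl(raw, voff, count, 4L, endian),
    `12` = .rd_dbl(raw, voff, count, 8L, endian),
    NULL)
  list(tag = tag, values = values)
}

# Parse a GeoTIFF into list(values, cell_size_x, cell_size_y, origin, nodata).
# values is a numeric matrix, row 1 = northernmost row; nodata not yet applied.
read_geotiff <- function(path) {
  raw <- readBin(path, what = "raw", n = file.size(path))
  order_mark <- rawToChar(raw[1:2])
  endian <- if (order_mark == "II") "little" else if (order_mark == "MM") "big"
    else stop("not a TIFF file (bad byte-order mark): ", path)
  if (.rd_int(raw, 2L, 1L, 2L, FALSE, endian) != 42L)
    stop("not a TIFF file (bad magic number): ", path)
  ifd_off <- .rd_int(raw, 4L, 1L, 4L, FALSE, endian)
  n_entries <- .rd_int(raw, ifd_off, 1L, 2L, FALSE, endian)
  tags <- list()
  for (i in seq_len(n_entries)) {
    e <- .read_ifd_entry(raw, ifd_off + 2L + (i - 1L) * 12L, endian)
    tags[[as.character(e$tag)]] <- e$values
  }
  if (!is.null(.rd_int(raw, ifd_off + 2L + n_entries * 12L, 1L, 4L, FALSE, endian)) &&
      .rd_int(raw, ifd_off + 2L + n_entries * 12L, 1L, 4L, FALSE, endian) != 0L)
    stop("multi-image (multi-directory) TIFF not supported: ", path)

  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stop("TIFF missing required tag ", tag, ": ", path)
      default
    } else v
  }
  width  <- need(256); height <- need(257)
  spp <- need(277, 1L)
  if (spp != 1L)
    stop("multi-band GeoTIFF not supported (", spp, " samples per pixel): ", path)
  if (need(259, 1L) != 1L)
    stop("compressed TIFF not supported (compression code ", need(259), "): ", path)
  if (!is.null(tags[["322"]]) || !is.null(tags[["324"]]))
    stop("tiled TIFF not supported: ", path)
  bps <- need(258, 1L)
  sample_format <- need(339, 1L)

  # georeferencing: pixel scale + tiepoint, or an axis-aligned transformation
  if (!is.null(tags[["34264"]])) {
    m <- tags[["34264"]]  # 4x4 row-major
    if (abs(m[2]) > 1e-12 || abs(m[5]) > 1e-12)
      stop("rotated affine transform not supported (off-diagonal terms ",
           signif(m[2], 6), ", ", signif(m[5], 6), ")")
    sx <- m[1]; sy <- -m[6]; ox <- m[4]; oy <- m[8]
  } else {
    scale <- tags[["33550"]]
    tie   <- tags[["33922"]]
    if (is.null(scale) || is.null(tie))
      stop("GeoTIFF lacks georeferencing (ModelPixelScale/ModelTiepoint): ", path)
    sx <- scale[1]; sy <- scale[2]
    ox <- tie[4] - tie[1] * sx
    oy <- tie[5] + tie[2] * sy
  }

  nodata <- if (!is.null(tags[["42113"]]))
    suppressWarnings(as.numeric(gsub("\\0", "", tags[["42113"]]))) else NA_real_

  strip_offsets <- need(273)
  strip_counts  <- need(279)
  rows_per_strip <- need(278, height)
  pixel_size <- bps %/% 8L
  vals <- numeric(0)
  for (s in seq_along(strip_offsets)) {
    n_px <- strip_counts[s] %/% pixel_size
    chunk <- raw[(strip_offsets[s] + 1):(strip_offsets[s] + strip_counts[s])]
    v <- if (sample_format == 3L)
      readBin(chunk, "double", n = n_px, size = pixel_size, endian = endian)
    else
      readBin(chunk, "integer", n = n_px, size = pixel_size,
              signed = sample_format == 2L || pixel_size == 4L, endian = endian)
    vals <- c(vals, as.numeric(v))
  }
  if (length(vals) != width * height)
    stop("TIFF pixel count mismatch: got ", length(vals), ", expected ",
         width * height)
  values <- matrix(vals, nrow = height, ncol = width, byrow = TRUE)
  list(values = values, cell_size_x = sx, cell_size_y = sy,
       origin = c(ox, oy), nodata = nodata)
}

.ifd_entry <- function(tag, type, count, value_field) {
  c(writeBin(as.integer(tag), raw(), size = 2, endian = "little"),
    writeBin(as.integer(type), raw(), size = 2, endian = "little"),
    writeBin(as.integer(count), raw(), size = 4, endian = "little"),
    value_field)
}

.inline <- function(x, size) {
  r <- writeBin(as.integer(x), raw(), size = size, endian = "little")
  c(r, raw(4L - length(r)))
}

# Write a single-band float GeoTIFF (uncompressed, one strip, little-endian).
# `values`: matrix (row 1 = top); NA cells written as `nodata` when given.
# `cell_size` may be length 2 (dx, dy) to write non-square cells (fixtures).
write_geotiff <- function(values, path, cell_size, origin,
                          nodata = NULL, dtype = c("float64", "float32")) {
  dtype <- match.arg(dtype)
  cell_size <- rep_len(cell_size, 2)
  nr <- nrow(values); nc <- ncol(values)
  px_size <- if (dtype == "float64") 8L else 4L
  v <- as.vector(t(values))  # row-major
  if (!is.null(nodata)) v[is.na(v)] <- nodata
  else if (anyNA(v)) stop("grid has nodata cells but no nodata value declared")

  pix <- writeBin(v, raw(), size = px_size, endian = "little")
  data_off <- 8L
  nbytes <- length(pix)
  ifd_off <- data_off + nbytes

  nodata_str <- if (!is.null(nodata)) {
    s <- charToRaw(formatC(nodata, format = "g", digits = 17))
    c(s, as.raw(0L))  # NUL-terminated ASCII
  } else NULL

  entries <- list(
    list(256, 4, 1, nc), list(257, 4, 1, nr), list(258, 3, 1, px_size * 8L),
    list(259, 3, 1, 1), list(262, 3, 1, 1), list(273, 4, 1, data_off),
    list(277, 3, 1, 1), list(278, 4, 1, nr), list(279, 4, 1, nbytes),
    list(284, 3, 1, 1), list(339, 3, 1, 3))
  n_extra_tags <- 2L + (!is.null(nodata_str))
  n_entries <- length(entries) + n_extra_tags
  # out-of-line region follows the IFD (2 + 12n + 4 bytes)
  extra_off <- ifd_off + 2L + 12L * n_entries + 4L

  scale_bytes <- writeBin(c(cell_size[1], cell_size[2], 0), raw(), size = 8,
                          endian = "little")
  tie_bytes <- writeBin(c(0, 0, 0, origin[1], origin[2], 0), raw(), size = 8,
                        endian = "little")
  scale_off <- extra_off
  tie_off <- scale_off + length(scale_bytes)
  nodata_off <- tie_off + length(tie_bytes)

  ifd <- writeBin(as.integer(n_entries), raw(), size = 2, endian = "little")
  for (e in entries) {
    size <- c(`3` = 2L, `4` = 4L)[as.character(e[[2]])]
    ifd <- c(ifd, .ifd_entry(e[[1]], e[[2]], e[[3]], .inline(e[[4]], size)))
  }
  ifd <- c(ifd,
    .ifd_entry(33550, 12, 3, .inline(scale_off, 4L)),
    .ifd_entry(33922, 12, 6, .inline(tie_off, 4L)))
  if (!is.null(nodata_str))
    ifd <- c(ifd, .ifd_entry(42113, 2, length(nodata_str), .inline(nodata_off, 4L)))
  ifd <- c(ifd, writeBin(0L, raw(), size = 4, endian = "little"))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"),
             writeBin(42L, raw(), size = 2, endian = "little"),
             writeBin(as.integer(ifd_off), raw(), size = 4, endian = "little"),
             pix, ifd, scale_bytes, tie_bytes,
             if (!is.null(nodata_str)) nodata_str else raw(0)),
           con)
  invisible(path)
}
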