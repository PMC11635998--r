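#' Read and write single-band float64 GeoTIFF
#'
#' A deliberately small GeoTIFF dialect: little-endian, uncompressed, one
#' 64-bit IEEE floating-point band in a single strip, georeferenced with
#' `ModelPixelScale` + `ModelTiepoint` tags and the nodata value in the
#' conventional ASCII nodata tag. Doubles survive the round trip bit-exactly.
#' The reader accepts only this dialect and fails with a named-field error on
#' anything else (compressed, tiled, multi-band, integer TIFFs).
#'
#' @param path File path ending in `.tif` or `.tiff`.
#' @param raster An [enm_raster()] to write.
#' @param crs_label Label attached to the grid on read.
#' @return `read_gtiff()` returns an `enm_raster`; `write_gtiff()` returns
#'   `path` invisibly.
#' @export
write_gtiff <- function(raster, path) {
  grid <- raster$grid
  vals <- raster$values
  vals[!raster$mask] <- grid$nodata_value
  data <- as.vector(t(vals))  # row-major, north to south
  n_bytes <- length(data) * 8L

  strip_off <- 8L
  scale_off <- strip_off + n_bytes
  tie_off <- scale_off + 24L
  nodata_str <- charToRaw(paste0(format(grid$nodata_value), "\x01"))
  nodata_str[length(nodata_str)] <- as.raw(0L)
  nodata_off <- tie_off + 48L
  nodata_len <- length(nodata_str)
  ifd_off <- nodata_off + nodata_len
  if (ifd_off %% 2L == 1L) {  # IFD must be word-aligned
    nodata_str <- c(nodata_str, as.raw(0L))
    nodata_len <- nodata_len + 1L
    ifd_off <- ifd_off + 1L
  }

  y_max <- grid$y_min + grid$n_rows * grid$cell_size
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd_off, con, size = 4, endian = "little")
  writeBin(data, con, size = 8, endian = "little")
  writeBin(c(grid$cell_size, grid$cell_size, 0), con, size = 8, endian = "little")
  writeBin(c(0, 0, 0, grid$x_min, y_max, 0), con, size = 8, endian = "little")
  writeBin(nodata_str, con)

  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L && count == 1L) {  # SHORT packed into the value field
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  entries <- list(
    list(256L, 3L, 1L, grid$n_cols),       # ImageWidth
    list(257L, 3L, 1L, grid$n_rows),       # ImageLength
    list(258L, 3L, 1L, 64L),               # BitsPerSample
    list(259L, 3L, 1L, 1L),                # Compression: none
    list(262L, 3L, 1L, 1L),                # Photometric: min-is-black
    list(273L, 4L, 1L, strip_off),         # StripOffsets
    list(277L, 3L, 1L, 1L),                # SamplesPerPixel
    list(278L, 4L, 1L, grid$n_rows),       # RowsPerStrip
    list(279L, 4L, 1L, n_bytes),           # StripByteCounts
    list(339L, 3L, 1L, 3L),                # SampleFormat: IEEE float
    list(33550L, 12L, 3L, scale_off),      # ModelPixelScale
    list(33922L, 12L, 6L, tie_off),        # ModelTiepoint
    list(42113L, 2L, nodata_len, nodata_off)  # nodata (ASCII)
  )
  writeBin(length(entries), con, size = 2, endian = "little")
  for (e in entries) entry(e[[1]], e[[2]], e[[3]], e[[4]])
  writeBin(0L, con, size = 4, endian = "little")  # no next IFD
  invisible(path)
}

#' @rdname write_gtiff
#' @export
read_gtiff <- function(path, crs_label = "planar") {
  raw <- readBin(path, "raw", file.size(path))
  u16 <- function(off) readBin(raw[(off + 1):(off + 2)], "integer", size = 2,
                               signed = FALSE, endian = "little")
  u32 <- function(off) readBin(raw[(off + 1):(off + 4)], "integer", size = 4,
                               endian = "little")
  dbl <- function(off, n) readBin(raw[(off + 1):(off + 8 * n)], "double",
                                  n = n, size = 8, endian = "little")
  if (rawToChar(raw[1:2]) != "II" || u16(2) != 42L) {
    stop("not a little-endian TIFF (bad magic)", call. = FALSE)
  }
  ifd <- u32(4)
  n_entries <- u16(ifd)
  tags <- list()
  for (k in seq_len(n_entries)) {
    off <- ifd + 2L + (k - 1L) * 12L
    tag <- u16(off); type <- u16(off + 2L); count <- u32(off + 4L)
    value <- if (type == 3L && count == 1L) u16(off + 8L) else u32(off + 8L)
    tags[[as.character(tag)]] <- list(type = type, count = count, value = value)
  }
  need <- function(tag, default = NULL) {
    t <- tags[[as.character(tag)]]
    if (is.null(t)) {
      if (!is.null(default)) return(list(value = default))
      stop(sprintf("TIFF missing required tag %d", tag), call. = FALSE)
    }
    t
  }
  n_cols <- need(256)$value
  n_rows <- need(257)$value
  if (need(258)$value != 64L) stop("unsupported TIFF: BitsPerSample != 64", call. = FALSE)
  if (need(259, 1L)$value != 1L) stop("unsupported TIFF: compressed", call. = FALSE)
  if (need(277, 1L)$value != 1L) stop("unsupported TIFF: multi-band", call. = FALSE)
  if (need(339)$value != 3L) stop("unsupported TIFF: SampleFormat != float", call. = FALSE)
  strip_off <- need(273)$value
  scale <- dbl(need(33550)$value, 3)
  tie <- dbl(need(33922)$value, 6)
  nodata <- -9999
  nd <- tags[["42113"]]
  if (!is.null(nd)) {
    s <- raw[(nd$value + 1):(nd$value + nd$count)]
    nodata <- as.numeric(rawToChar(s[s != as.raw(0)]))
  }
  data <- dbl(strip_off, n_rows * n_cols)
  m <- matrix(data, nrow = n_rows, ncol = n_cols, byrow = TRUE)
  y_max <- tie[5]
  grid <- grid_spec(
    n_rows = n_rows, n_cols = n_cols,
    x_min = tie[4], y_min = y_max - n_rows * scale[1],
    cell_size = scale[1], crs_label = crs_label, nodata_value = nodata
  )
  mask <- m != nodata
  m[!mask] <- NA_real_
  enm_raster(m, grid, mask)
}

#' Read or write a raster by file extension
#'
#' Dispatches to the `.asc` or GeoTIFF reader/writer on the extension.
#'
#' @param path File path (`.asc`, `.tif`, `.tiff`).
#' @param raster If supplied, written to `path`; otherwise `path` is read.
#' @param ... Passed to the format-specific function.
#' @return An `enm_raster` on read; `path` invisibly on write.
#' @export
raster_io <- function(path, raster = NULL, ...) {
  ext <- tolower(tools::file_ext(path))
  if (is.null(raster)) {
    switch(ext,
      asc = read_asc(path, ...),
      tif = ,
      tiff = read_gtiff(path, ...),
      stop(sprintf("unsupported raster extension '%s'", ext), call. = FALSE)
    )
  } else {
    switch(ext,
      asc = write_asc(raster, path, ...),
      tif = ,
      tiff = write_gtiff(raster, path),
      stop(sprintf("unsupported raster extension '%s'", ext), call. = FALSE)
    )
  }
}
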