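#' Read and write ESRI ASCII grids
#'
#' The `.asc` dialect used throughout: a six-line header
#' (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`)
#' followed by rows of values north to south. Values are written with six
#' decimal places by default; pass `digits = NULL` for full `%.17g` precision
#' (bit-exact round trips). Masked cells are written as the nodata value
#' literally as given.
#'
#' @param path File path ending in `.asc`.
#' @param raster An [enm_raster()] to write.
#' @param digits Decimal places for written values, or `NULL` for full
#'   precision.
#' @param crs_label Label attached to the grid on read (the format itself
#'   carries no CRS).
#' @return `read_asc()` returns an `enm_raster`; `write_asc()` returns `path`
#'   invisibly.
#' @export
read_asc <- function(path, crs_label = "planar") {
  lines <- readLines(path, n = 6L)
  keys <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "NODATA_value")
  header <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) >= 2) header[[parts[1]]] <- suppressWarnings(as.numeric(parts[2]))
  }
  for (k in keys) {
    if (is.null(header[[k]]) || is.na(header[[k]])) {
      stop(sprintf("malformed .asc header: missing or non-numeric field '%s'", k),
           call. = FALSE)
    }
  }
  if (header$cellsize <= 0) {
    stop("malformed .asc header: cellsize must be positive", call. = FALSE)
  }
  grid <- grid_spec(
    n_rows = header$nrows, n_cols = header$ncols,
    x_min = header$xllcorner, y_min = header$yllcorner,
    cell_size = header$cellsize, crs_label = crs_label,
    nodata_value = header$NODATA_value
  )
  vals <- scan(path, skip = 6L, quiet = TRUE)
  if (length(vals) != grid$n_rows * grid$n_cols) {
    stop(sprintf(".asc body has %d values, expected %d", length(vals),
                 grid$n_rows * grid$n_cols), call. = FALSE)
  }
  m <- matrix(vals, nrow = grid$n_rows, ncol = grid$n_cols, byrow = TRUE)
  mask <- m != grid$nodata_value
  m[!mask] <- NA_real_
  enm_raster(m, grid, mask)
}

#' @rdname read_asc
#' @export
write_asc <- function(raster, path, digits = 6) {
  grid <- raster$grid
  fmt <- if (is.null(digits)) "%.17g" else paste0("%.", digits, "f")
  vals <- raster$values
  out <- matrix(sprintf(fmt, vals), nrow(vals), ncol(vals))
  out[!raster$mask] <- format(grid$nodata_value)
  header <- c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcorner %.10g", grid$x_min),
    sprintf("yllcorner %.10g", grid$y_min),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %s", format(grid$nodata_value))
  )
  body <- apply(out, 1, paste, collapse = " ")
  writeLines(c(header, body), path)
  invisible(path)
}
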