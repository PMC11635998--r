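#' Single-band raster bound to a grid
#'
#' A thin matrix-plus-grid container. `values` is an `n_rows x n_cols` numeric
#' matrix with row 1 the northernmost row; masked (invalid) cells are `NA` in
#' memory and carry the grid's nodata value on file write.
#'
#' @param values Numeric matrix, `n_rows x n_cols`.
#' @param grid A [grid_spec()] with matching dimensions.
#' @param mask Optional logical matrix, `TRUE` for valid cells; defaults to
#'   `!is.na(values)`.
#' @return An object of class `enm_raster`.
#' @export
enm_raster <- function(values, grid, mask = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols) {
    stop(sprintf(
      "raster shape %d x %d does not match grid %d x %d",
      nrow(values), ncol(values), grid$n_rows, grid$n_cols
    ), call. = FALSE)
  }
  if (is.null(mask)) mask <- !is.na(values)
  stopifnot(identical(dim(mask), dim(values)))
  values[!mask] <- NA_real_
  structure(list(values = values, grid = grid, mask = mask),
            class = "enm_raster")
}

#' @export
print.enm_raster <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf(
    "<enm_raster> %d x %d (%d valid cells), range [%g, %g]\n",
    x$grid$n_rows, x$grid$n_cols, sum(x$mask),
    if (length(v)) min(v) else NA, if (length(v)) max(v) else NA
  ))
  invisible(x)
}

#' Raster values as a tidy table
#'
#' @param x An `enm_raster`.
#' @param ... Unused.
#' @return A tibble with `row`, `col`, `x`, `y`, `value` for valid cells.
#' @export
as_tibble.enm_raster <- function(x, ...) {
  idx <- which(x$mask, arr.ind = TRUE)
  ctr <- cell_center(x$grid, idx[, 1], idx[, 2])
  tibble::tibble(
    row = idx[, 1], col = idx[, 2],
    x = ctr$x, y = ctr$y,
    value = x$values[idx]
  )
}

#' Per-cell area raster
#'
#' Planar grids get the constant `cell_size^2` (map units squared). Lon/lat
#' grids get the spherical quadrilateral area in km^2,
#' `(111.19493 * cell)^2 * cos(lat_center)`, so zonal tables report km^2 as
#' area tables conventionally do.
#'
#' @param grid A [grid_spec()].
#' @return An `enm_raster` of per-cell areas.
#' @export
cell_area_raster <- function(grid) {
  if (is_lonlat(grid)) {
    lat <- cell_center(grid, seq_len(grid$n_rows), 1)$y
    km_per_deg <- 6371 * pi / 180
    row_area <- (km_per_deg * grid$cell_size)^2 * cos(lat * pi / 180)
    vals <- matrix(rep(row_area, grid$n_cols), grid$n_rows, grid$n_cols)
  } else {
    vals <- matrix(grid$cell_size^2, grid$n_rows, grid$n_cols)
  }
  enm_raster(vals, grid)
}

#' Named stack of co-registered rasters
#'
#' @param ... Named `enm_raster` objects (or a single named list of them)
#'   sharing one grid. The joint mask is the intersection of layer masks.
#' @return An object of class `env_stack`: a named list of rasters with the
#'   shared `grid` and joint `mask` as attributes.
#' @export
env_stack <- function(...) {
  layers <- list(...)
  if (length(layers) == 1 && is.list(layers[[1]]) &&
      !inherits(layers[[1]], "enm_raster")) {
    layers <- layers[[1]]
  }
  if (length(layers) == 0) stop("empty stack", call. = FALSE)
  if (is.null(names(layers)) || any(names(layers) == "")) {
    stop("all stack layers must be named", call. = FALSE)
  }
  grid <- layers[[1]]$grid
  mask <- layers[[1]]$mask
  for (l in layers) {
    stopifnot(inherits(l, "enm_raster"))
    if (!same_grid(l$grid, grid)) {
      stop("stack layers are not co-registered", call. = FALSE)
    }
    mask <- mask & l$mask
  }
  structure(layers, grid = grid, mask = mask, class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  g <- attr(x, "grid")
  cat(sprintf("<env_stack> %d layers on %d x %d grid: %s\n",
              length(x), g$n_rows, g$n_cols,
              paste(names(x), collapse = ", ")))
  invisible(x)
}

stack_grid <- function(stack) attr(stack, "grid")
stack_mask <- function(stack) attr(stack, "mask")

# layer values at the jointly valid cells, as a cells x layers matrix;
# `cells` are linear indices into the value matrix (column-major, as which()).
stack_matrix <- function(stack, cells = NULL) {
  mask <- stack_mask(stack)
  if (is.null(cells)) cells <- which(mask)
  out <- vapply(stack, function(l) l$values[cells], numeric(length(cells)))
  if (length(cells) == 1L) out <- matrix(out, nrow = 1, dimnames = list(NULL, names(stack)))
  colnames(out) <- names(stack)
  out
}

cells_to_rowcol <- function(grid, cells) {
  arr <- arrayInd(cells, c(grid$n_rows, grid$n_cols))
  list(row = arr[, 1], col = arr[, 2])
}
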