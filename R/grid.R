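#' Define a raster grid
#'
#' A grid specification fixes the geometry every raster, occurrence set and
#' planning lattice in a pipeline shares: cell-center registration with row 1
#' as the northernmost row. The cell center of row `i`, column `j` is at
#' `(x_min + (j - 0.5) * cell_size, y_min + (n_rows - i + 0.5) * cell_size)`.
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param x_min,y_min Coordinates of the lower-left corner of the grid, in map
#'   units (degrees for lon/lat grids, arbitrary planar units otherwise).
#' @param cell_size Cell edge length in map units; cells are square.
#' @param crs_label Free-text label; anything containing `"lon"` is treated as
#'   geographic (lon/lat) by distance and area helpers, everything else as
#'   planar.
#' @param nodata_value Value written for masked cells in file output.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, x_min = 0, y_min = 0, cell_size = 1,
                      crs_label = "planar", nodata_value = -9999) {
  stopifnot(n_rows >= 1, n_cols >= 1)
  if (!is.finite(cell_size) || cell_size <= 0) {
    stop("`cell_size` must be a positive number", call. = FALSE)
  }
  structure(
    list(
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      x_min = as.numeric(x_min), y_min = as.numeric(y_min),
      cell_size = as.numeric(cell_size),
      crs_label = crs_label, nodata_value = as.numeric(nodata_value)
    ),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %d x %d cells, cell size %g, origin (%g, %g), crs '%s'\n",
    x$n_rows, x$n_cols, x$cell_size, x$x_min, x$y_min, x$crs_label
  ))
  invisible(x)
}

is_lonlat <- function(grid) grepl("lon", grid$crs_label, ignore.case = TRUE)

#' Cell-center coordinates
#'
#' @param grid A [grid_spec()].
#' @param i,j Row and column indices (1-based; row 1 is northernmost).
#'   Vectors are recycled against each other.
#' @return A tibble with columns `x` and `y`.
#' @export
cell_center <- function(grid, i, j) {
  tibble::tibble(
    x = grid$x_min + (j - 0.5) * grid$cell_size,
    y = grid$y_min + (grid$n_rows - i + 0.5) * grid$cell_size
  )
}

#' Map points to grid cells
#'
#' Points are assigned by `floor((x - x_min) / cell_size)`; a point lying
#' exactly on an upper or right cell edge belongs to the lower-index cell, so
#' the grid's own outer top/right boundary is still inside the grid.
#'
#' @param grid A [grid_spec()].
#' @param x,y Point coordinates (equal-length vectors).
#' @return A tibble with 1-based `row` (from the north) and `col` columns;
#'   `NA` for points outside the grid extent.
#' @export
point_to_cell <- function(grid, x, y) {
  ux <- (x - grid$x_min) / grid$cell_size
  uy <- (y - grid$y_min) / grid$cell_size
  j0 <- floor(ux)
  i0 <- floor(uy)  # 0-based from the south
  on_right_edge <- ux == j0 & j0 > 0
  on_top_edge <- uy == i0 & i0 > 0
  j0[on_right_edge] <- j0[on_right_edge] - 1
  i0[on_top_edge] <- i0[on_top_edge] - 1
  outside <- ux < 0 | uy < 0 | j0 >= grid$n_cols | i0 >= grid$n_rows
  row <- grid$n_rows - i0
  col <- j0 + 1
  row[outside] <- NA_integer_
  col[outside] <- NA_integer_
  tibble::tibble(row = as.integer(row), col = as.integer(col))
}

same_grid <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$x_min - b$x_min) < tol && abs(a$y_min - b$y_min) < tol &&
    abs(a$cell_size - b$cell_size) < tol
}
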