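#' Synthetic study scenario
#'
#' Defines a reproducible synthetic world: `n_layers` spatially smooth
#' environmental fields with a controlled correlation structure, a known
#' logistic true-suitability surface over them, and everything downstream
#' (occurrences, scenario shifts, planning lattices) derived with known ground
#' truth. The default scenario used throughout the package's own tests has two
#' informative layers and one pure-noise layer on a 200 x 200 planar grid with
#' 200 sampled occurrences — large enough for stable sample correlations and
#' importance rankings, small enough to run everywhere.
#'
#' @param grid A [grid_spec()].
#' @param layer_names Names for the layers (length gives `n_layers`).
#' @param target_corr Symmetric positive semi-definite correlation matrix with
#'   unit diagonal (defaults to identity).
#' @param smoothness Gaussian smoothing length-scale in cells.
#' @param beta Coefficient vector for the true logistic suitability:
#'   intercept followed by one coefficient per layer (applied to standardized
#'   layers).
#' @param seed Integer seed; every generator below is a pure function of
#'   `(scenario, seed)`.
#' @return An object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(grid = grid_spec(200, 200),
                               layer_names = c("bio_a", "bio_b", "noise_c"),
                               target_corr = NULL,
                               smoothness = 6,
                               beta = c(0, 2, 1.5, 0),
                               seed = 1L) {
  k <- length(layer_names)
  if (is.null(target_corr)) target_corr <- diag(k)
  target_corr <- as.matrix(target_corr)
  if (!isTRUE(all.equal(target_corr, t(target_corr))) ||
      any(abs(diag(target_corr) - 1) > 1e-12)) {
    stop("`target_corr` must be symmetric with unit diagonal", call. = FALSE)
  }
  ev <- eigen(target_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stop("`target_corr` must be positive semi-definite", call. = FALSE)
  }
  if (length(beta) != k + 1) {
    stop("`beta` must have length n_layers + 1 (intercept first)", call. = FALSE)
  }
  structure(
    list(grid = grid, layer_names = layer_names, n_layers = k,
         target_corr = target_corr, smoothness = smoothness,
         beta = beta, seed = as.integer(seed)),
    class = "synthetic_scenario"
  )
}

# Separable Gaussian smoothing of a matrix, kernel truncated at 3 sigma,
# renormalized at the edges so the field keeps its scale.
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(-half:half, sd = sigma)
  kern <- kern / sum(kern)
  smooth_dim <- function(mat) {
    n <- nrow(mat)
    out <- matrix(0, n, ncol(mat))
    for (o in -half:half) {
      w <- kern[o + half + 1]
      src <- pmin(pmax(seq_len(n) + o, 1L), n)  # clamp at edges
      out <- out + w * mat[src, , drop = FALSE]
    }
    out
  }
  smooth_dim(t(smooth_dim(m)))
}

#' Generate a correlated stack of smooth environmental fields
#'
#' Each layer starts as Gaussian-filtered white noise at the scenario's
#' length-scale, is standardized, and the layers are then linearly mixed by
#' the Cholesky factor of `target_corr` so their sample correlations converge
#' to the target as the grid grows.
#'
#' @param scenario A [synthetic_scenario()].
#' @return An [env_stack()] with the scenario's layer names.
#' @export
generate_env_stack <- function(scenario) {
  g <- scenario$grid
  k <- scenario$n_layers
  set.seed(scenario$seed)
  fields <- lapply(seq_len(k), function(l) {
    f <- gaussian_smooth(matrix(stats::rnorm(g$n_rows * g$n_cols),
                                g$n_rows, g$n_cols),
                         scenario$smoothness)
    (f - mean(f)) / stats::sd(f)
  })
  if (k > 1) {
    L <- t(chol(scenario$target_corr))
    z <- vapply(fields, as.vector, numeric(g$n_rows * g$n_cols))
    y <- z %*% t(L)
    fields <- lapply(seq_len(k), function(l) matrix(y[, l], g$n_rows, g$n_cols))
  }
  names(fields) <- scenario$layer_names
  env_stack(lapply(fields, enm_raster, grid = g))
}

#' True suitability surface and its derived truth set
#'
#' Standardizes each layer over its valid cells, applies the logistic model
#' `1 / (1 + exp(-(b0 + sum(b_k * z_k))))`, and derives the binary truth at
#' the conventional 0.5 probability cut together with the centroid (mean of
#' cell centers) of the suitable cells.
#'
#' @param stack An [env_stack()].
#' @param beta Intercept plus one coefficient per layer.
#' @param reference Optional stack whose layer means and standard deviations
#'   are used for the standardization instead of `stack`'s own — pass the
#'   base-period stack when evaluating truth on a shifted scenario, so that a
#'   pure translation of the fields translates the suitable region exactly.
#' @return A list of class `truth_set`: `true_suitability` and `true_binary`
#'   rasters and `true_centroid` (named vector `x`, `y`).
#' @export
true_suitability <- function(stack, beta, reference = NULL) {
  g <- stack_grid(stack)
  mask <- stack_mask(stack)
  if (!any(mask)) stop("all cells masked", call. = FALSE)
  stopifnot(length(beta) == length(stack) + 1)
  cells <- which(mask)
  x <- stack_matrix(stack, cells)
  ref <- if (is.null(reference)) x else stack_matrix(reference)
  mu <- colMeans(ref)
  sds <- apply(ref, 2, stats::sd)
  z <- sweep(sweep(x, 2, mu), 2, ifelse(sds > 0, sds, 1), "/")
  z[, sds == 0] <- 0
  eta <- beta[1] + as.vector(z %*% beta[-1])
  suit <- 1 / (1 + exp(-eta))
  vals <- matrix(NA_real_, g$n_rows, g$n_cols)
  vals[cells] <- suit
  suit_r <- enm_raster(vals, g, mask)
  bin <- matrix(NA_real_, g$n_rows, g$n_cols)
  bin[cells] <- as.numeric(suit >= 0.5)
  bin_r <- enm_raster(bin, g, mask)
  on_cells <- cells[suit >= 0.5]
  centroid <- c(x = NA_real_, y = NA_real_)
  if (length(on_cells)) {
    rc <- cells_to_rowcol(g, on_cells)
    ctr <- cell_center(g, rc$row, rc$col)
    centroid <- c(x = mean(ctr$x), y = mean(ctr$y))
  }
  structure(list(true_suitability = suit_r, true_binary = bin_r,
                 true_centroid = centroid),
            class = "truth_set")
}

#' Sample presence points proportional to suitability
#'
#' Cells are drawn with probability proportional to the true suitability and
#' each point is placed uniformly within its drawn cell.
#'
#' @param truth A `truth_set` from [true_suitability()].
#' @param n Number of points (>= 1).
#' @param seed Integer seed.
#' @param species Species label for the records.
#' @return An occurrence tibble (see [occurrence_set()]).
#' @export
sample_occurrences <- function(truth, n, seed = 1L, species = "synthetic") {
  stopifnot(n >= 1)
  suit <- truth$true_suitability
  g <- suit$grid
  cells <- which(suit$mask)
  p <- suit$values[cells]
  if (all(p <= 0)) stop("suitability is identically zero", call. = FALSE)
  set.seed(seed)
  drawn <- cells[sample.int(length(cells), n, replace = TRUE, prob = p)]
  rc <- cells_to_rowcol(g, drawn)
  x <- g$x_min + (rc$col - 1 + stats::runif(n)) * g$cell_size
  y <- g$y_min + (g$n_rows - rc$row + stats::runif(n)) * g$cell_size
  occurrence_set(species, x, y, source_tag = "synthetic")
}

#' Shift a stack to emulate a future scenario
#'
#' Translates every layer by `(di, dj)` cells (positive `di` moves content
#' south, positive `dj` east), masking cells with no source, then adds a
#' per-layer offset. With `delta = 0` the true suitable region and its
#' centroid move by exactly `(di, dj)` cells.
#'
#' @param stack An [env_stack()].
#' @param shift_cells Integer vector `c(di, dj)`.
#' @param delta Per-layer additive offsets (recycled).
#' @return A shifted [env_stack()].
#' @export
shift_scenario <- function(stack, shift_cells = c(0L, 0L), delta = 0) {
  g <- stack_grid(stack)
  di <- as.integer(shift_cells[1]); dj <- as.integer(shift_cells[2])
  if (abs(di) >= g$n_rows || abs(dj) >= g$n_cols) {
    stop("shift larger than the grid", call. = FALSE)
  }
  delta <- rep_len(delta, length(stack))
  shifted <- purrr::imap(stack, function(layer, nm) {
    k <- match(nm, names(stack))
    src <- layer$values
    out <- matrix(NA_real_, g$n_rows, g$n_cols)
    dst_rows <- seq_len(g$n_rows) ; dst_cols <- seq_len(g$n_cols)
    ok_r <- dst_rows - di >= 1 & dst_rows - di <= g$n_rows
    ok_c <- dst_cols - dj >= 1 & dst_cols - dj <= g$n_cols
    out[dst_rows[ok_r], dst_cols[ok_c]] <-
      src[dst_rows[ok_r] - di, dst_cols[ok_c] - dj] + delta[k]
    enm_raster(out, g)
  })
  env_stack(shifted)
}

#' Planning-unit lattice with adjacency and cost fractions
#'
#' Tiles the grid into `unit_rows x unit_cols` rectangular planning units,
#' builds the rook-adjacency boundary list (shared boundary length = shared
#' edge length in map units), and draws per-unit prohibited-land-cover and
#' protected-area fractions from a Beta(1, 4) so most units are cheap and a
#' few are expensive. Unit ids run row-major from the northwest.
#'
#' @param grid A [grid_spec()] whose dimensions are divisible by the lattice.
#' @param unit_rows,unit_cols Lattice dimensions; `unit_rows * unit_cols >= 2`.
#' @param seed Integer seed for the cost fractions.
#' @return A list of class `planning_lattice`: `units` tibble (`id`, `row`,
#'   `col`, `area`, `prohibited_frac`, `protected_frac`, `cost`, `status`),
#'   `boundaries` tibble (`id1`, `id2`, `boundary`), and `unit_raster`
#'   labelling every grid cell with its unit id.
#' @export
generate_planning_lattice <- function(grid, unit_rows, unit_cols, seed = 1L) {
  if (unit_rows * unit_cols < 2) stop("need at least 2 planning units", call. = FALSE)
  if (unit_rows > grid$n_rows || unit_cols > grid$n_cols) {
    stop("lattice finer than the raster grid", call. = FALSE)
  }
  if (grid$n_rows %% unit_rows != 0 || grid$n_cols %% unit_cols != 0) {
    stop("grid dimensions must be divisible by the lattice", call. = FALSE)
  }
  cell_r <- grid$n_rows %/% unit_rows
  cell_c <- grid$n_cols %/% unit_cols
  ids <- matrix(seq_len(unit_rows * unit_cols), unit_rows, unit_cols, byrow = TRUE)
  unit_raster <- enm_raster(
    ids[rep(seq_len(unit_rows), each = cell_r),
        rep(seq_len(unit_cols), each = cell_c)], grid)
  set.seed(seed)
  n <- unit_rows * unit_cols
  prohibited <- stats::rbeta(n, 1, 4)
  protected <- stats::rbeta(n, 1, 4)
  units <- tibble::tibble(
    id = seq_len(n),
    row = rep(seq_len(unit_rows), each = unit_cols),
    col = rep(seq_len(unit_cols), times = unit_rows),
    area = cell_r * cell_c * grid$cell_size^2,
    prohibited_frac = prohibited,
    protected_frac = protected,
    cost = pu_cost(prohibited, protected),
    status = "available"
  )
  # rook adjacency: horizontal neighbours share a vertical edge and vice versa
  horiz <- tidyr::expand_grid(r = seq_len(unit_rows), c = seq_len(unit_cols - 1))
  vert <- tidyr::expand_grid(r = seq_len(unit_rows - 1), c = seq_len(unit_cols))
  b1 <- tibble::tibble(
    id1 = (horiz$r - 1) * unit_cols + horiz$c,
    id2 = (horiz$r - 1) * unit_cols + horiz$c + 1,
    boundary = cell_r * grid$cell_size
  )
  b2 <- tibble::tibble(
    id1 = (vert$r - 1) * unit_cols + vert$c,
    id2 = vert$r * unit_cols + vert$c,
    boundary = cell_c * grid$cell_size
  )
  boundaries <- dplyr::arrange(dplyr::bind_rows(b1, b2), id1, id2)
  structure(list(units = units, boundaries = boundaries,
                 unit_raster = unit_raster),
            class = "planning_lattice")
}
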