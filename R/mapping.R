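#' Zonal area table for a classified habitat map
#'
#' Sums per-cell areas by region and habitat class and reports, per region,
#' the three class areas, the percentage of the region that is suitable, and
#' the region's suitable share of the whole domain, with a grand-total row —
#' the conventional layout of per-city suitability tables.
#'
#' @param classified A `classified_map`.
#' @param regions An `enm_raster` of integer region labels, co-registered
#'   with `classified`.
#' @param cell_area An `enm_raster` of per-cell areas (e.g.
#'   [cell_area_raster()]), or a single number.
#' @param legend Optional named character vector mapping label to region
#'   name; labels present in `regions` but absent from a supplied legend are
#'   an error.
#' @return A tibble of class `region_table`: `region`, `unsuitable`,
#'   `sub_suitable`, `suitable`, `pct_suitable_in_region`,
#'   `pct_suitable_of_domain`, plus a final `Total` row.
#' @export
area_table <- function(classified, regions, cell_area = 1, legend = NULL) {
  if (!same_grid(classified$grid, regions$grid)) {
    stop("regions raster is not co-registered with the classified map",
         call. = FALSE)
  }
  cells <- which(classified$mask & regions$mask)
  lab <- regions$values[cells]
  cls <- classified$values[cells]
  area <- if (inherits(cell_area, "enm_raster")) {
    cell_area$values[cells]
  } else {
    rep(cell_area, length(cells))
  }
  if (!is.null(legend)) {
    missing_lab <- setdiff(unique(lab), as.numeric(names(legend)))
    if (length(missing_lab)) {
      stop(sprintf("region label(s) absent from the legend: %s",
                   paste(missing_lab, collapse = ", ")), call. = FALSE)
    }
  }
  df <- tibble::tibble(label = lab, cls = cls, area = area) |>
    dplyr::group_by(label) |>
    dplyr::summarise(
      unsuitable = sum(area[cls == 0]),
      sub_suitable = sum(area[cls == 1]),
      suitable = sum(area[cls == 2]),
      .groups = "drop"
    ) |>
    dplyr::arrange(label)
  domain_total <- sum(df$unsuitable + df$sub_suitable + df$suitable)
  df <- df |>
    dplyr::mutate(
      region = if (is.null(legend)) as.character(label) else
        unname(legend[as.character(label)]),
      pct_suitable_in_region =
        100 * suitable / (unsuitable + sub_suitable + suitable),
      pct_suitable_of_domain = 100 * suitable / domain_total
    ) |>
    dplyr::select(region, unsuitable, sub_suitable, suitable,
                  pct_suitable_in_region, pct_suitable_of_domain)
  total <- tibble::tibble(
    region = "Total",
    unsuitable = sum(df$unsuitable),
    sub_suitable = sum(df$sub_suitable),
    suitable = sum(df$suitable),
    pct_suitable_in_region = 100 * sum(df$suitable) / domain_total,
    pct_suitable_of_domain = 100 * sum(df$suitable) / domain_total
  )
  out <- dplyr::bind_rows(df, total)
  class(out) <- c("region_table", class(out))
  out
}

# change-map category codes
.change_codes <- c(never_present = 0, expansion = 1, contraction = 2,
                   no_change_present = 3)

#' Range-change map between two classified maps
#'
#' Binarizes both maps by the presence rule, then labels each valid cell
#' expansion (absent to present), contraction (present to absent), no-change
#' present, or never present. The four categories partition the valid
#' domain.
#'
#' @param base,future `classified_map`s on the same grid.
#' @param presence_rule `"suitable_only"` (class 2) or `"suitable_or_sub"`
#'   (classes 1-2), applied to both maps.
#' @return An `enm_raster` of class `change_map` with codes 0-3 (legend in
#'   attribute `codes`).
#' @export
change_map <- function(base, future,
                       presence_rule = c("suitable_or_sub", "suitable_only")) {
  presence_rule <- match.arg(presence_rule)
  if (!same_grid(base$grid, future$grid)) {
    stop("base and future maps are on different grids", call. = FALSE)
  }
  lo <- if (presence_rule == "suitable_only") 2 else 1
  mask <- base$mask & future$mask
  b <- base$values >= lo
  f <- future$values >= lo
  b[is.na(b)] <- FALSE
  f[is.na(f)] <- FALSE
  v <- matrix(NA_real_, nrow(base$values), ncol(base$values))
  v[mask] <- .change_codes["never_present"]
  v[mask & !b & f] <- .change_codes["expansion"]
  v[mask & b & !f] <- .change_codes["contraction"]
  v[mask & b & f] <- .change_codes["no_change_present"]
  out <- enm_raster(v, base$grid, mask)
  attr(out, "codes") <- .change_codes
  attr(out, "presence_rule") <- presence_rule
  class(out) <- c("change_map", class(out))
  out
}

#' Areas and rates of range change
#'
#' Category areas plus percentage rates with the union of base and future
#' presence (expansion + contraction + stable) as denominator, the
#' convention behind expansion/stability/loss percentages.
#'
#' @param cmap A [change_map()].
#' @param cell_area Per-cell area raster or single number.
#' @return A tibble: `category`, `area`, `rate_pct` (`NA` for
#'   `never_present`).
#' @export
change_stats <- function(cmap, cell_area = 1) {
  cells <- which(cmap$mask)
  area <- if (inherits(cell_area, "enm_raster")) {
    cell_area$values[cells]
  } else {
    rep(cell_area, length(cells))
  }
  v <- cmap$values[cells]
  areas <- vapply(.change_codes, function(code) sum(area[v == code]),
                  numeric(1))
  union_area <- areas["expansion"] + areas["contraction"] +
    areas["no_change_present"]
  if (union_area == 0) stop("no present cells in either map", call. = FALSE)
  tibble::tibble(
    category = names(.change_codes),
    area = unname(areas),
    rate_pct = ifelse(names(.change_codes) == "never_present", NA_real_,
                      100 * unname(areas) / union_area)
  )
}

#' Area-weighted centroid of a habitat class
#'
#' @param classified A `classified_map`.
#' @param class_rule `"suitable_only"` or `"suitable_or_sub"`.
#' @param cell_area Per-cell area raster or single number (area weighting
#'   keeps lon/lat and planar behaviour consistent).
#' @return A named vector `c(x, y)` of the centroid in map units.
#' @export
centroid <- function(classified, class_rule = "suitable_only",
                     cell_area = 1) {
  cells <- class_cells(classified, class_rule)
  if (!length(cells)) stop("no cells in the requested class", call. = FALSE)
  w <- if (inherits(cell_area, "enm_raster")) {
    cell_area$values[cells]
  } else {
    rep(cell_area, length(cells))
  }
  rc <- cells_to_rowcol(classified$grid, cells)
  ctr <- cell_center(classified$grid, rc$row, rc$col)
  c(x = sum(ctr$x * w) / sum(w), y = sum(ctr$y * w) / sum(w))
}

#' Centroid migration track across scenario maps
#'
#' Computes the class centroid of each labelled map and the consecutive and
#' base-relative displacement distances and bearings. Lon/lat grids use
#' haversine distance on a 6371 km sphere and initial bearings from north,
#' clockwise; planar grids use Euclidean distance and the same bearing
#' convention.
#'
#' @param maps Named list of `classified_map`s on one shared grid; the first
#'   entry is the base.
#' @param class_rule `"suitable_only"` or `"suitable_or_sub"`.
#' @param cell_area Per-cell areas for the centroid weighting.
#' @return A tibble of class `centroid_track`: `label`, `x`, `y`,
#'   `dist_from_prev`, `dist_from_base`, `bearing_from_prev` (degrees;
#'   distances in km on lon/lat grids, map units otherwise).
#' @export
centroid_track <- function(maps, class_rule = "suitable_only",
                           cell_area = 1) {
  stopifnot(length(maps) >= 2)
  if (is.null(names(maps))) names(maps) <- paste0("map", seq_along(maps))
  g <- maps[[1]]$grid
  for (m in maps) {
    if (!same_grid(m$grid, g)) stop("maps share no common grid", call. = FALSE)
  }
  cents <- purrr::imap(maps, function(m, nm) {
    tryCatch(centroid(m, class_rule, cell_area),
             error = function(e) stop(sprintf("map '%s': %s", nm,
                                              conditionMessage(e)),
                                      call. = FALSE))
  })
  xy <- do.call(rbind, cents)
  lonlat <- is_lonlat(g)
  dist_fun <- function(a, b) {
    if (lonlat) {
      geosphere::distHaversine(a, b, r = 6371) # km
    } else {
      sqrt(sum((b - a)^2))
    }
  }
  bear_fun <- function(a, b) {
    if (all(a == b)) return(NA_real_)
    if (lonlat) {
      (geosphere::bearing(a, b) + 360) %% 360
    } else {
      (atan2(b[1] - a[1], b[2] - a[2]) * 180 / pi + 360) %% 360
    }
  }
  n <- nrow(xy)
  out <- tibble::tibble(
    label = names(maps),
    x = xy[, 1], y = xy[, 2],
    dist_from_prev = c(NA, vapply(2:n, function(i)
      dist_fun(xy[i - 1, ], xy[i, ]), numeric(1))),
    dist_from_base = c(0, vapply(2:n, function(i)
      dist_fun(xy[1, ], xy[i, ]), numeric(1))),
    bearing_from_prev = c(NA, vapply(2:n, function(i)
      bear_fun(xy[i - 1, ], xy[i, ]), numeric(1)))
  )
  class(out) <- c("centroid_track", class(out))
  out
}

#' Zonal table from per-region class areas
#'
#' Convenience wrapper: given per-region areas already aggregated by habitat
#' class (for example a published summary table), lays them out as a
#' one-cell-per-class raster per region and routes them through
#' [area_table()], so the percentage accounting is computed by the same
#' machinery as for full rasters.
#'
#' @param areas A data frame with columns `region` (or `city`),
#'   `unsuitable_km2`, `subsuitable_km2`, `suitable_km2`.
#' @return A `region_table` tibble (see [area_table()]).
#' @export
region_table_from_areas <- function(areas) {
  nm <- if ("region" %in% names(areas)) areas$region else areas$city
  n <- nrow(areas)
  g <- grid_spec(n, 3)
  cls <- classify(enm_raster(matrix(rep(c(0, 0.5, 1), each = n), n, 3), g),
                  threshold_set(0.4, 0.8))
  reg <- enm_raster(matrix(rep(seq_len(n), 3), n, 3), g)
  area <- enm_raster(cbind(areas$unsuitable_km2, areas$subsuitable_km2,
                           areas$suitable_km2), g)
  tab <- area_table(cls, reg, cell_area = area,
                    legend = stats::setNames(nm, seq_len(n)))
  tab
}
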