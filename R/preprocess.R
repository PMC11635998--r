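#' Thin occurrences to one record per grid cell
#'
#' Keeps the first record encountered in each occupied cell and moves it to
#' the cell center, the standard de-duplication that limits spatial
#' autocorrelation and sampling-bias overfitting before model fitting.
#' Idempotent: thinning a thinned set is a no-op.
#'
#' @param occ Occurrence tibble (`species`, `longitude`, `latitude`).
#' @param grid A [grid_spec()]; all points must fall inside its extent.
#' @return A thinned occurrence tibble, one record per occupied cell, at cell
#'   centers.
#' @export
thin_occurrences <- function(occ, grid) {
  cells <- point_to_cell(grid, occ$longitude, occ$latitude)
  bad <- which(is.na(cells$row))
  if (length(bad)) {
    stop(sprintf("occurrence point (%g, %g) falls outside the grid extent",
                 occ$longitude[bad[1]], occ$latitude[bad[1]]), call. = FALSE)
  }
  key <- (cells$row - 1L) * grid$n_cols + cells$col
  keep <- !duplicated(key)
  ctr <- cell_center(grid, cells$row[keep], cells$col[keep])
  out <- occurrence_set(occ$species[keep], ctr$x, ctr$y,
                        source_tag = attr(occ, "source_tag") %||% "")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Drop collinear layers by pairwise Pearson correlation
#'
#' Within each variable group (e.g. climate / terrain / soil), walks the
#' layers in priority order and drops any layer whose absolute Pearson
#' correlation with an already-kept layer of the same group reaches
#' `r_threshold`. Correlations are computed over all jointly valid grid
#' cells. Cross-group pairs never trigger drops. Zero-variance layers are
#' dropped outright (their correlation is undefined).
#'
#' @param stack An [env_stack()].
#' @param groups Named list mapping group name to layer names; defaults to a
#'   single group holding every layer.
#' @param r_threshold Absolute-correlation cutoff (default 0.85: pairs with
#'   `|r| >= 0.85` lose their lower-priority member).
#' @param ranking Layer names in decreasing priority; defaults to stack
#'   order. In a full pipeline, descending preliminary percent contribution
#'   is the natural ranking.
#' @return A tibble of class `variable_selection` with columns `layer`,
#'   `kept`, `reason` (`NA` for kept layers, otherwise
#'   `"correlated_with:<layer>"` or `"zero_variance"`), and `r_with_kept`.
#' @export
pearson_filter <- function(stack, groups = NULL, r_threshold = 0.85,
                           ranking = NULL) {
  layer_names <- names(stack)
  if (is.null(groups)) groups <- list(all = layer_names)
  if (is.null(ranking)) ranking <- layer_names
  if (!setequal(unlist(groups), layer_names)) {
    stop("`groups` must partition the stack's layer names", call. = FALSE)
  }
  if (!setequal(ranking, layer_names)) {
    stop("`ranking` must cover all layers", call. = FALSE)
  }
  x <- stack_matrix(stack)
  sds <- apply(x, 2, stats::sd)
  cors <- suppressWarnings(stats::cor(x))
  group_of <- stats::setNames(
    rep(names(groups), lengths(groups)), unlist(groups))

  kept <- character(0)
  rows <- purrr::map(ranking, function(nm) {
    if (sds[nm] == 0) {
      return(tibble::tibble(layer = nm, kept = FALSE,
                            reason = "zero_variance", r_with_kept = NA_real_))
    }
    rivals <- kept[group_of[kept] == group_of[nm] & sds[kept] > 0]
    r <- if (length(rivals)) abs(cors[nm, rivals]) else numeric(0)
    if (length(r) && max(r) >= r_threshold) {
      culprit <- rivals[which.max(r)]
      tibble::tibble(layer = nm, kept = FALSE,
                     reason = paste0("correlated_with:", culprit),
                     r_with_kept = max(r))
    } else {
      kept <<- c(kept, nm)
      tibble::tibble(layer = nm, kept = TRUE, reason = NA_character_,
                     r_with_kept = if (length(r)) max(r) else NA_real_)
    }
  })
  out <- dplyr::bind_rows(rows)
  out <- out[match(layer_names, out$layer), ]
  class(out) <- c("variable_selection", class(out))
  out
}

#' Prescreen layers by preliminary-model contribution
#'
#' Fits one default maximum-entropy model (regularization multiplier 1, all
#' five feature classes) and drops layers whose percent contribution and
#' permutation importance are both below `pc_threshold` percent — the
#' conventional "low or zero contribution" cut applied before calibration.
#'
#' @param occ Thinned occurrence tibble (>= 5 records).
#' @param stack An [env_stack()].
#' @param pc_threshold Percent cutoff (default 1).
#' @param seed Seed for the background sample and the permutation importance.
#' @return A `variable_selection` tibble with columns `layer`, `kept`,
#'   `reason`, `pc`, `pi`.
#' @export
contribution_prescreen <- function(occ, stack, pc_threshold = 1, seed = 1L) {
  if (nrow(occ) < 5) {
    stop("need at least 5 occurrences after thinning", call. = FALSE)
  }
  model <- fit_maxent(occ, stack, fc = c("L", "Q", "P", "T", "H"),
                      rm = 1, seed = seed)
  imp <- variable_importance(model, seed = seed)
  out <- tibble::tibble(
    layer = imp$layer,
    kept = !(imp$percent_contribution < pc_threshold &
               imp$permutation_importance < pc_threshold),
    reason = ifelse(imp$percent_contribution < pc_threshold &
                      imp$permutation_importance < pc_threshold,
                    "low_contribution", NA_character_),
    pc = imp$percent_contribution,
    pi = imp$permutation_importance
  )
  out <- out[match(names(stack), out$layer), ]
  class(out) <- c("variable_selection", class(out))
  out
}
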