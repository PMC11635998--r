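#' Percent contribution and permutation importance
#'
#' Percent contribution (PC) attributes the gain accumulated along the
#' fitting path to layers (each optimizer step's objective decrease is shared
#' among features in proportion to their weight change times gradient, and
#' product features split evenly between their two layers), normalized to
#' 100. Permutation importance (PI) is the drop in training AUC (presence vs
#' background) when one layer's values are permuted jointly across the
#' presence and background cells, normalized to 100.
#'
#' @param model A fitted `maxent_model`.
#' @param seed Seed for the permutation.
#' @return A tibble of class `importance_table`: `layer`,
#'   `percent_contribution`, `permutation_importance`.
#' @export
variable_importance <- function(model, seed = 1L) {
  if (is.null(model$weights)) stop("model is not fitted", call. = FALSE)
  layers <- model$layer_names
  lw <- feature_layer_weights(model$features)
  # features the L1 penalty dropped from the final model carry no contribution
  attrib <- model$gain_attrib * (abs(model$weights) > 1e-8)
  pc_raw <- stats::setNames(numeric(length(layers)), layers)
  for (f in seq_along(lw)) {
    for (nm in names(lw[[f]])) {
      pc_raw[nm] <- pc_raw[nm] + lw[[f]][nm] * attrib[f]
    }
  }
  pc <- if (sum(pc_raw) > 0) 100 * pc_raw / sum(pc_raw) else
    rep(100 / length(layers), length(layers))

  x_pres <- model$design$x_pres
  x_bg <- model$design$x_bg
  m <- nrow(x_pres)
  eta_pres <- model_eta(model, x_pres)
  eta_bg <- model_eta(model, x_bg)
  auc_full <- auc_scores(eta_pres, eta_bg)
  set.seed(seed)
  drops <- vapply(layers, function(nm) {
    comb <- c(x_pres[, nm], x_bg[, nm])
    perm <- sample(comb)
    xp <- x_pres; xb <- x_bg
    xp[, nm] <- perm[seq_len(m)]
    xb[, nm] <- perm[-seq_len(m)]
    auc_perm <- auc_scores(model_eta(model, xp), model_eta(model, xb))
    max(0, auc_full - auc_perm)
  }, numeric(1))
  pi <- if (sum(drops) > 0) 100 * drops / sum(drops) else
    rep(100 / length(layers), length(layers))

  out <- tibble::tibble(layer = layers,
                        percent_contribution = unname(pc[layers]),
                        permutation_importance = unname(pi))
  class(out) <- c("importance_table", class(out))
  out
}

#' Jackknife gain test over layers
#'
#' For every layer, refits the model with only that layer's features
#' (`with_only_gain`) and with every feature except that layer's
#' (`without_gain`), holding the background sample, normalization and
#' regularization bounds fixed so the gains are nested-comparable:
#' `without_gain <= full_model_gain` always holds.
#'
#' @param occ Occurrence tibble.
#' @param stack An [env_stack()].
#' @param fc,rm,n_knots Model settings, as in [fit_maxent()].
#' @param background_size,seed Background controls, as in [fit_maxent()].
#' @return A tibble of class `jackknife_table` (`layer`, `with_only_gain`,
#'   `without_gain`) with the full-model gain as attribute
#'   `full_model_gain`.
#' @export
jackknife <- function(occ, stack, fc = c("L", "Q"), rm = 1, n_knots = 10,
                      background_size = 10000, seed = 1L) {
  features <- expand_features(stack, fc, n_knots)
  design <- build_design(occ, stack, features, background_size, seed)
  beta <- reg_bounds(features, design$f_pres, rm)
  # tight tolerance so the sub-model gains are nested-comparable
  tol <- 1e-7
  full <- fit_core(design$f_pres, design$f_bg, beta,
                   max_iter = 3000, tol = tol)
  layers <- names(stack)
  if (length(layers) < 2) {
    out <- tibble::tibble(layer = layers, with_only_gain = full$training_gain,
                          without_gain = NA_real_)
  } else {
    involves <- purrr::map(feature_layer_weights(features), names)
    sub_gain <- function(cols) {
      if (!length(cols)) return(0)
      fit_core(design$f_pres[, cols, drop = FALSE],
               design$f_bg[, cols, drop = FALSE],
               beta[cols], max_iter = 3000, tol = tol)$training_gain
    }
    out <- purrr::map_dfr(layers, function(nm) {
      only <- which(vapply(involves, function(v) all(v == nm), logical(1)))
      without <- which(vapply(involves, function(v) !nm %in% v, logical(1)))
      tibble::tibble(layer = nm,
                     with_only_gain = sub_gain(only),
                     without_gain = sub_gain(without))
    })
  }
  attr(out, "full_model_gain") <- full$training_gain
  class(out) <- c("jackknife_table", class(out))
  out
}

#' Single-factor response curve
#'
#' Fits a model on one layer's features alone and traces its logistic output
#' across the layer's background range — the conventional way to read off a
#' species' tolerated range for one variable.
#'
#' @param occ Occurrence tibble.
#' @param stack An [env_stack()].
#' @param layer Layer name (must be non-constant).
#' @param fc,rm,n_knots,background_size,seed As in [fit_maxent()].
#' @param grid_points Number of evenly spaced evaluation values.
#' @return A tibble of class `response_curve` (`value`, `logistic`) with the
#'   fitted single-layer model as attribute `model`.
#' @export
response_curve <- function(occ, stack, layer, fc = c("L", "Q"), rm = 1,
                           n_knots = 10, grid_points = 100,
                           background_size = 10000, seed = 1L) {
  stopifnot(layer %in% names(stack))
  sub <- env_stack(stats::setNames(list(stack[[layer]]), layer))
  rng <- range(stack[[layer]]$values[stack[[layer]]$mask])
  if (diff(rng) == 0) stop(sprintf("layer '%s' is constant", layer), call. = FALSE)
  model <- fit_maxent(occ, sub, fc = fc, rm = rm, n_knots = n_knots,
                      background_size = background_size, seed = seed)
  vals <- seq(rng[1], rng[2], length.out = grid_points)
  x <- matrix(vals, ncol = 1, dimnames = list(NULL, layer))
  raw <- exp(model_eta(model, x) - model$log_normalizer)
  reh <- raw * exp(model$entropy)
  out <- tibble::tibble(value = vals, logistic = reh / (1 + reh))
  attr(out, "model") <- model
  class(out) <- c("response_curve", class(out))
  out
}
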