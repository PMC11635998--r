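#' Enumerate candidate model settings
#'
#' Crosses a regularization-multiplier grid with every non-empty subset of
#' the feature classes. The conventional calibration grid — multipliers 0.1
#' to 4 in steps of 0.1 against all 31 non-empty subsets of
#' \{L, Q, P, T, H\} — yields 1240 candidates.
#'
#' @param rm_min,rm_max,rm_step Multiplier grid (ascending, positive step).
#' @param classes Feature classes to form subsets of.
#' @return A tibble (`rm`, `fc`) in deterministic order: `rm` ascending, then
#'   subset bitmask ascending (bit k = `classes[k]`).
#' @export
enumerate_candidates <- function(rm_min = 0.1, rm_max = 4, rm_step = 0.1,
                                 classes = c("L", "Q", "P", "T", "H")) {
  stopifnot(rm_min <= rm_max, rm_step > 0)
  if (length(classes) == 0) stop("empty feature-class set", call. = FALSE)
  n_rm <- floor((rm_max - rm_min) / rm_step + 1e-9) + 1
  rms <- round(rm_min + (seq_len(n_rm) - 1) * rm_step, 10)
  masks <- seq_len(2^length(classes) - 1)
  subsets <- vapply(masks, function(m) {
    paste(classes[bitwAnd(m, 2^(seq_along(classes) - 1)) > 0], collapse = "")
  }, character(1))
  tidyr::expand_grid(rm = rms, fc = subsets)
}

#' Split occurrences into train and test sets
#'
#' A seeded shuffle puts `round(test_fraction * n)` records in the test set.
#'
#' @param occ Occurrence tibble (>= 2 records when `test_fraction > 0`).
#' @param test_fraction Fraction in `[0, 1)`.
#' @param seed Integer seed.
#' @return A list with tibbles `train` and `test`.
#' @export
split_occurrences <- function(occ, test_fraction = 0.3, seed = 1L) {
  stopifnot(test_fraction >= 0, test_fraction < 1)
  n <- nrow(occ)
  if (test_fraction > 0 && n < 2) {
    stop("need at least 2 records to split", call. = FALSE)
  }
  n_test <- round(test_fraction * n)
  set.seed(seed)
  idx <- sample.int(n)
  test_idx <- sort(idx[seq_len(n_test)])
  list(train = occ[setdiff(seq_len(n), test_idx), ],
       test = occ[test_idx, ])
}

# scores of a suitability map at occurrence points
scores_at_points <- function(prediction, occ) {
  g <- prediction$grid
  rc <- point_to_cell(g, occ$longitude, occ$latitude)
  s <- prediction$values[cbind(rc$row, rc$col)]
  if (anyNA(s)) stop("occurrence point off the valid prediction area", call. = FALSE)
  s
}

#' Partial ROC test
#'
#' The partial-ROC bootstrap of niche-model evaluation: the AUC of the model
#' curve above sensitivity `1 - E`, divided by the area of the random
#' expectation line over the same range, resampling test points with
#' replacement; `p` is the fraction of bootstrap ratios at or below 1.
#'
#' @param prediction Suitability `enm_raster`.
#' @param test_points Occurrence tibble of test presences (>= 5).
#' @param E Acceptable omission, in (0, 0.5).
#' @param n_iter Bootstrap iterations.
#' @param resample_prop Proportion of test points drawn per iteration.
#' @param seed Integer seed.
#' @return A list: `auc_ratio_mean`, `p`, and the per-iteration `ratios`.
#' @export
partial_roc <- function(prediction, test_points, E = 0.05, n_iter = 500,
                        resample_prop = 0.5, seed = 1L) {
  stopifnot(E > 0, E < 0.5)
  bg_vals <- prediction$values[prediction$mask]
  if (stats::sd(bg_vals) == 0) {
    stop("prediction is constant; ROC undefined", call. = FALSE)
  }
  test_scores <- scores_at_points(prediction, test_points)
  if (length(test_scores) < 5 && n_iter > 1) {
    stop("need at least 5 test points", call. = FALSE)
  }
  # threshold sweep over background quantiles; x = fractional predicted area
  thr <- unique(stats::quantile(bg_vals, seq(0, 1, length.out = 201),
                                names = FALSE, type = 7))
  area <- vapply(thr, function(t) mean(bg_vals >= t), numeric(1))
  ratio_of <- function(scores) {
    sens <- vapply(thr, function(t) mean(scores >= t), numeric(1))
    keep <- sens >= 1 - E
    if (sum(keep) < 2) return(NA_real_)
    o <- order(area[keep])
    x <- area[keep][o]; y <- sens[keep][o]
    auc_mod <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
    auc_rand <- sum(diff(x) * (utils::head(x, -1) + utils::tail(x, -1)) / 2)
    if (auc_rand <= 0) return(NA_real_)
    auc_mod / auc_rand
  }
  set.seed(seed)
  n_draw <- max(1L, round(resample_prop * length(test_scores)))
  ratios <- vapply(seq_len(n_iter), function(i) {
    s <- if (n_iter == 1 && resample_prop == 1) test_scores else
      sample(test_scores, n_draw, replace = TRUE)
    ratio_of(s)
  }, numeric(1))
  ratios <- ratios[is.finite(ratios)]
  list(auc_ratio_mean = mean(ratios),
       p = mean(ratios <= 1),
       ratios = ratios)
}

#' Omission rate at a training-percentile threshold
#'
#' The threshold is the `E`-th percentile (linear interpolation) of the
#' prediction at training presences; the omission rate is the fraction of
#' test presences scoring below it.
#'
#' @param prediction Suitability `enm_raster`.
#' @param train_points,test_points Occurrence tibbles.
#' @param E Training omission level in `[0, 0.5)` (default 0.05).
#' @return The omission rate in `[0, 1]`.
#' @export
omission_rate <- function(prediction, train_points, test_points, E = 0.05) {
  stopifnot(E >= 0, E < 0.5)
  if (nrow(test_points) == 0) stop("empty test set", call. = FALSE)
  train_scores <- scores_at_points(prediction, train_points)
  test_scores <- scores_at_points(prediction, test_points)
  thr <- stats::quantile(train_scores, E, names = FALSE, type = 7)
  mean(test_scores < thr)
}

#' Small-sample-corrected AIC of a fitted model
#'
#' `AICc = 2k - 2 lnL + 2k(k+1)/(n-k-1)` with `k` the number of nonzero
#' weights and `lnL` the log-likelihood of the presences under the raw
#' output normalized over the whole valid study area.
#'
#' @param model A `maxent_model`.
#' @param presence_points Occurrence tibble (defaults to the training
#'   presences stored in the model).
#' @param stack Stack defining the study area for normalization; defaults to
#'   the model's background.
#' @return The AICc value, or `NA` with attribute `reason` when
#'   `n <= k + 1`.
#' @export
aicc <- function(model, presence_points = NULL, stack = NULL) {
  k <- sum(abs(model$weights) > 1e-8)
  if (!is.null(stack)) {
    cells <- which(stack_mask(stack))
    eta_area <- model_eta(model, stack_matrix(stack, cells))
    pred <- predict(model, stack, type = "raw")
    pres_raw <- if (is.null(presence_points)) {
      idx <- match(model$design$pres_cells, cells)
      exp(eta_area[idx] - model$log_normalizer)
    } else {
      scores_at_points(pred, presence_points)
    }
    log_z_area <- logsumexp(eta_area) - model$log_normalizer
    lnL <- sum(log(pres_raw) - log_z_area)
    n <- length(pres_raw)
  } else {
    eta_bg <- as.vector(model$design$f_bg %*% model$weights)
    eta_pres <- as.vector(model$design$f_pres %*% model$weights)
    lnL <- sum(eta_pres - logsumexp(eta_bg))
    n <- length(eta_pres)
  }
  if (n <= k + 1) {
    out <- NA_real_
    attr(out, "reason") <- sprintf("n = %d <= k + 1 = %d", n, k + 1)
    return(out)
  }
  2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1)
}

#' Evaluate a grid of candidate models
#'
#' Fits every candidate on the training split, scores it by partial ROC,
#' omission rate, and AICc, and reports one tidy row per candidate.
#'
#' @param occ Thinned occurrence tibble.
#' @param stack An [env_stack()].
#' @param candidates Tibble from [enumerate_candidates()].
#' @param test_fraction Held-out fraction for OR and partial ROC.
#' @param E Omission level.
#' @param n_iter,resample_prop Partial-ROC bootstrap controls.
#' @param seed Integer seed (split, background, bootstrap).
#' @param n_knots,background_size As in [fit_maxent()].
#' @return A tibble of class `candidate_metrics`: `rm`, `fc`,
#'   `proc_auc_ratio`, `proc_p`, `omission_rate`, `aicc`, `delta_aicc`,
#'   `n_params`.
#' @export
calibrate_candidates <- function(occ, stack, candidates = enumerate_candidates(),
                                 test_fraction = 0.3, E = 0.05,
                                 n_iter = 100, resample_prop = 0.5,
                                 seed = 1L, n_knots = 10,
                                 background_size = 10000) {
  split <- split_occurrences(occ, test_fraction, seed)
  rows <- purrr::pmap(candidates, function(rm, fc) {
    fcs <- strsplit(fc, "")[[1]]
    model <- fit_maxent(split$train, stack, fc = fcs, rm = rm,
                        n_knots = n_knots,
                        background_size = background_size, seed = seed)
    pred <- predict(model, stack, type = "logistic")
    pr <- partial_roc(pred, split$test, E = E, n_iter = n_iter,
                      resample_prop = resample_prop, seed = seed)
    tibble::tibble(
      rm = rm, fc = fc,
      proc_auc_ratio = pr$auc_ratio_mean, proc_p = pr$p,
      omission_rate = omission_rate(pred, split$train, split$test, E),
      aicc = as.numeric(aicc(model, stack = stack)),
      n_params = sum(abs(model$weights) > 1e-8)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$delta_aicc <- out$aicc - min(out$aicc, na.rm = TRUE)
  class(out) <- c("candidate_metrics", class(out))
  out
}

#' Select the winning candidate
#'
#' Keeps statistically significant candidates (`proc_p < alpha`), then those
#' with omission rate at most `or_max`, and returns the minimum-AICc
#' survivor (`delta_aicc = 0`). Ties go to fewer parameters, then lower
#' multiplier, then lexicographic feature-class string.
#'
#' @param metrics A `candidate_metrics` tibble.
#' @param alpha Significance level (default 0.05).
#' @param or_max Maximum admissible omission rate (default 0.05).
#' @param fallback_min_or When no significant candidate meets `or_max`,
#'   fall back to the significant candidates with the lowest observed
#'   omission rate instead of failing — the usual pragmatic rule when the
#'   omission criterion is narrowly missed. Default `FALSE`: strict failure.
#' @return The selected row of `metrics` (with `delta_aicc` recomputed over
#'   the admissible set).
#' @export
select_model <- function(metrics, alpha = 0.05, or_max = 0.05,
                         fallback_min_or = FALSE) {
  if (nrow(metrics) == 0) stop("empty metrics table", call. = FALSE)
  sig <- metrics[!is.na(metrics$proc_p) & metrics$proc_p < alpha, ]
  adm <- sig[sig$omission_rate <= or_max, ]
  if (nrow(adm) == 0 && fallback_min_or && nrow(sig) > 0) {
    adm <- sig[sig$omission_rate == min(sig$omission_rate), ]
  }
  if (nrow(adm) == 0) {
    near <- metrics[order(metrics$proc_p, metrics$omission_rate), ]
    near <- utils::head(near, 3)
    stop(paste0(
      "no admissible model (significant with omission <= ", or_max,
      "); nearest misses: ",
      paste(sprintf("rm=%g fc=%s (p=%.3f, OR=%.3f)", near$rm, near$fc,
                    near$proc_p, near$omission_rate), collapse = "; ")
    ), call. = FALSE)
  }
  adm$delta_aicc <- adm$aicc - min(adm$aicc, na.rm = TRUE)
  best <- adm[order(adm$delta_aicc, adm$n_params, adm$rm, adm$fc), ][1, ]
  best
}

#' Replicate fits of one candidate
#'
#' Refits the chosen candidate over `n_rep` seeded resplits and averages the
#' logistic maps cellwise — the usual way a final model is reported
#' (mean map over replicates, with per-replicate train/test AUC).
#'
#' @param occ Occurrence tibble.
#' @param stack An [env_stack()].
#' @param rm,fc Candidate settings (`fc` a string such as `"QTH"`).
#' @param n_rep Number of replicates.
#' @param test_fraction Held-out fraction per replicate.
#' @param seed Base seed; replicate r uses `seed + r`.
#' @param ... Passed to [fit_maxent()].
#' @return A list of class `replicate_result`: `mean_map`, `auc` tibble
#'   (`replicate`, `train_auc`, `test_auc`), `auc_mean`, `auc_sd`.
#' @export
replicate_fit <- function(occ, stack, rm, fc, n_rep = 10,
                          test_fraction = 0.3, seed = 1L, ...) {
  stopifnot(n_rep >= 1)
  fcs <- strsplit(fc, "")[[1]]
  maps <- vector("list", n_rep)
  aucs <- purrr::map_dfr(seq_len(n_rep), function(r) {
    split <- split_occurrences(occ, test_fraction, seed + r)
    model <- fit_maxent(split$train, stack, fc = fcs, rm = rm,
                        seed = seed + r, ...)
    pred <- predict(model, stack, type = "logistic")
    maps[[r]] <<- pred
    bg_scores <- pred$values[pred$mask]
    train_auc <- auc_scores(scores_at_points(pred, split$train), bg_scores)
    test_auc <- if (nrow(split$test)) {
      auc_scores(scores_at_points(pred, split$test), bg_scores)
    } else NA_real_
    tibble::tibble(replicate = r, train_auc = train_auc, test_auc = test_auc)
  })
  g <- maps[[1]]$grid
  arr <- vapply(maps, function(m) m$values, maps[[1]]$values)
  mean_vals <- apply(arr, c(1, 2), mean)
  structure(
    list(mean_map = enm_raster(mean_vals, g, maps[[1]]$mask),
         maps = maps, auc = aucs,
         auc_mean = mean(aucs$train_auc), auc_sd = stats::sd(aucs$train_auc)),
    class = "replicate_result"
  )
}
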