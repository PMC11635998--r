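#' Maximum training sensitivity plus specificity threshold
#'
#' Scans candidate thresholds (the union of observed scores) and returns the
#' one maximizing sensitivity + specificity, with presences positive,
#' background negative and predicted-positive defined as `score >= t`. Ties
#' go to the lowest threshold.
#'
#' @param presence_scores,background_scores Non-empty numeric vectors.
#' @return The MTSS threshold.
#' @export
mtss_threshold <- function(presence_scores, background_scores) {
  stopifnot(length(presence_scores) > 0, length(background_scores) > 0)
  cand <- sort(unique(c(presence_scores, background_scores)))
  if (length(cand) < 2) stop("all scores identical; threshold degenerate", call. = FALSE)
  ss <- vapply(cand, function(t) {
    mean(presence_scores >= t) + mean(background_scores < t)
  }, numeric(1))
  cand[which.max(ss)]  # which.max returns the first (lowest) maximizer
}

#' Balance threshold (training omission, predicted area, threshold value)
#'
#' Minimizes `6 * omission(t) + 0.04 * cumulative(t) + 1.6 * area(t)` over
#' candidate thresholds taken from the map's cells, where `omission` is the
#' fraction of training presences scoring below `t`, `cumulative` is the
#' cumulative output of the candidate cell, and `area` the fraction of valid
#' cells at or above `t`. The weights follow the balance rule of the
#' reference maximum-entropy implementation; they are exposed so other
#' balances can be tried. Ties go to the lowest threshold.
#'
#' @param presence_scores Logistic scores at training presences (non-empty).
#' @param logistic_values,cumulative_values Co-indexed vectors over the
#'   map's valid cells (e.g. from [predict.maxent_model()] with both output
#'   types).
#' @param weights The three balance weights.
#' @return The balance threshold on the logistic scale.
#' @export
balance_threshold <- function(presence_scores, logistic_values,
                              cumulative_values,
                              weights = c(omission = 6, cumulative = 0.04,
                                          area = 1.6)) {
  if (length(presence_scores) == 0) stop("empty presence scores", call. = FALSE)
  stopifnot(length(logistic_values) == length(cumulative_values))
  o <- order(logistic_values)
  cand <- logistic_values[o]
  cum <- cumulative_values[o]
  keep <- !duplicated(cand)
  cand <- cand[keep]; cum <- cum[keep]
  n <- length(logistic_values)
  obj <- vapply(seq_along(cand), function(k) {
    t <- cand[k]
    weights[1] * mean(presence_scores < t) +
      weights[2] * cum[k] +
      weights[3] * mean(logistic_values >= t)
  }, numeric(1))
  cand[which.min(obj)]
}

#' Threshold pair for three-class habitat maps
#'
#' @param tpt Balance ("TPT") threshold — lower class boundary.
#' @param mtss MTSS threshold — upper class boundary. Must satisfy
#'   `tpt <= mtss`; a reversed pair is an error, never silently reordered.
#' @return An object of class `threshold_set`.
#' @export
threshold_set <- function(tpt, mtss) {
  stopifnot(tpt >= 0, tpt <= 1, mtss >= 0, mtss <= 1)
  if (tpt > mtss) {
    stop(sprintf("tpt (%.4f) exceeds mtss (%.4f)", tpt, mtss), call. = FALSE)
  }
  structure(list(tpt = tpt, mtss = mtss), class = "threshold_set")
}

#' Classify a suitability map into three habitat classes
#'
#' Class 2 ("suitable") where the logistic output is at least the MTSS
#' threshold, class 1 ("sub-suitable") where it is at least the TPT threshold
#' but below MTSS, class 0 ("unsuitable") below TPT — boundaries closed at
#' the lower edge. Masked cells stay masked.
#'
#' @param prediction Logistic suitability `enm_raster`.
#' @param thresholds A [threshold_set()].
#' @return An `enm_raster` of class `classified_map` with values 0/1/2 and
#'   the thresholds attached as attribute `thresholds`.
#' @export
classify <- function(prediction, thresholds) {
  stopifnot(inherits(thresholds, "threshold_set"))
  v <- prediction$values
  cls <- ifelse(v >= thresholds$mtss, 2,
                ifelse(v >= thresholds$tpt, 1, 0))
  out <- enm_raster(cls, prediction$grid, prediction$mask)
  attr(out, "thresholds") <- thresholds
  class(out) <- c("classified_map", class(out))
  out
}

class_cells <- function(classified, class_rule = c("suitable_only",
                                                   "suitable_or_sub")) {
  class_rule <- match.arg(class_rule)
  lo <- if (class_rule == "suitable_only") 2 else 1
  which(classified$mask & classified$values >= lo)
}
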