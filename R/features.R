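#' Expand environmental layers into model features
#'
#' Builds the classic five feature classes of maximum-entropy niche models:
#' linear (L, the min-max normalized layer), quadratic (Q, its square),
#' product (P, pairwise products of normalized layers), threshold (T, step
#' functions at layer quantiles), and hinge (H, forward and reverse ramps at
#' layer quantiles). Normalization bounds and knots come from the layer
#' values over all valid cells; at prediction time values are clamped to
#' these bounds, so every feature maps into \[0, 1\].
#'
#' @param stack An [env_stack()].
#' @param fc Character vector of feature classes, a subset of
#'   `c("L","Q","P","T","H")`.
#' @param n_knots Number of quantile knots per layer for T and H features
#'   (default 10); duplicate and degenerate knots are dropped.
#' @return An object of class `feature_set`: a feature definition tibble
#'   (`name`, `class`, `layer1`, `layer2`, `knot`) plus the per-layer
#'   normalization table.
#' @export
expand_features <- function(stack, fc = c("L", "Q"), n_knots = 10) {
  fc <- match.arg(toupper(fc), c("L", "Q", "P", "T", "H"), several.ok = TRUE)
  layer_names <- names(stack)
  x <- stack_matrix(stack)
  norm <- tibble::tibble(
    layer = layer_names,
    min = apply(x, 2, min),
    max = apply(x, 2, max)
  )
  defs <- list()
  add <- function(d) defs[[length(defs) + 1]] <<- d
  rng <- stats::setNames(norm$max - norm$min, norm$layer)
  for (nm in layer_names) {
    if ("L" %in% fc) {
      add(tibble::tibble(name = paste0("L_", nm), class = "L",
                         layer1 = nm, layer2 = NA, knot = NA_real_))
    }
    if ("Q" %in% fc) {
      add(tibble::tibble(name = paste0("Q_", nm), class = "Q",
                         layer1 = nm, layer2 = NA, knot = NA_real_))
    }
    if (("T" %in% fc || "H" %in% fc) && rng[nm] == 0) {
      message(sprintf("layer '%s' is constant; no threshold/hinge features", nm))
      next
    }
    if ("T" %in% fc || "H" %in% fc) {
      probs <- seq_len(n_knots) / (n_knots + 1)
      knots <- unique(unname(stats::quantile(x[, nm], probs, type = 7)))
      if ("T" %in% fc) {
        tk <- knots[knots > norm$min[norm$layer == nm]]  # knot at min is constant 1
        for (k in tk) {
          add(tibble::tibble(name = sprintf("T_%s_%g", nm, k), class = "T",
                             layer1 = nm, layer2 = NA, knot = k))
        }
      }
      if ("H" %in% fc) {
        lo <- norm$min[norm$layer == nm]; hi <- norm$max[norm$layer == nm]
        for (k in knots[knots < hi]) {
          add(tibble::tibble(name = sprintf("Hf_%s_%g", nm, k), class = "H",
                             layer1 = nm, layer2 = NA, knot = k))
        }
        for (k in knots[knots > lo]) {
          add(tibble::tibble(name = sprintf("Hr_%s_%g", nm, k), class = "H",
                             layer1 = nm, layer2 = "reverse", knot = k))
        }
      }
    }
  }
  if ("P" %in% fc && length(layer_names) >= 2) {
    pairs <- utils::combn(layer_names, 2)
    for (p in seq_len(ncol(pairs))) {
      add(tibble::tibble(name = paste0("P_", pairs[1, p], "_x_", pairs[2, p]),
                         class = "P", layer1 = pairs[1, p],
                         layer2 = pairs[2, p], knot = NA_real_))
    }
  }
  defs <- dplyr::bind_rows(defs)
  structure(list(defs = defs, norm = norm, fc = fc, n_knots = n_knots),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d features (%s) over %d layers\n",
              nrow(x$defs), paste(x$fc, collapse = ""), nrow(x$norm)))
  invisible(x)
}

# Evaluate features on a cells x layers matrix of raw values.
# Values are clamped to the training min/max before transformation.
eval_features <- function(features, x) {
  norm <- features$norm
  defs <- features$defs
  x <- x[, norm$layer, drop = FALSE]
  xc <- x
  for (k in seq_len(ncol(xc))) {
    xc[, k] <- pmin(pmax(xc[, k], norm$min[k]), norm$max[k])
  }
  rng <- norm$max - norm$min
  xn <- sweep(xc, 2, norm$min)
  xn <- sweep(xn, 2, ifelse(rng > 0, rng, 1), "/")
  out <- matrix(0, nrow(x), nrow(defs))
  colnames(out) <- defs$name
  for (f in seq_len(nrow(defs))) {
    d <- defs[f, ]
    i1 <- match(d$layer1, norm$layer)
    out[, f] <- switch(d$class,
      L = xn[, i1],
      Q = xn[, i1]^2,
      P = xn[, i1] * xn[, match(d$layer2, norm$layer)],
      T = as.numeric(xc[, i1] >= d$knot),
      H = if (identical(d$layer2, "reverse")) {
        pmax(0, d$knot - xc[, i1]) / (d$knot - norm$min[i1])
      } else {
        pmax(0, xc[, i1] - d$knot) / (norm$max[i1] - d$knot)
      }
    )
  }
  out
}

# Layers each feature draws on, with weights (products split half and half).
feature_layer_weights <- function(features) {
  defs <- features$defs
  purrr::map2(defs$layer1, defs$layer2, function(l1, l2) {
    if (!is.na(l2) && l2 != "reverse") {
      stats::setNames(c(0.5, 0.5), c(l1, l2))
    } else {
      stats::setNames(1, l1)
    }
  })
}
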