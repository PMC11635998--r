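# Per-class regularization scales; hinge features are penalized lightly,
# thresholds heavily, mirroring the usual defaults of maximum-entropy SDMs.
.class_scale <- c(L = 1.0, Q = 1.0, P = 1.0, T = 2.0, H = 0.5)

logsumexp <- function(eta) {
  m <- max(eta)
  m + log(sum(exp(eta - m)))
}

# Mann-Whitney AUC of positive scores against negative scores (ties = 0.5).
auc_scores <- function(pos, neg) {
  r <- rank(c(pos, neg))
  m <- length(pos); n <- length(neg)
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

# L1-penalized Gibbs fit by proximal gradient (FISTA with backtracking).
# f_pres: m x J presence feature matrix; f_bg: N x J background matrix;
# beta: per-feature L1 bounds. Tracks per-feature gain attribution.
fit_core <- function(f_pres, f_bg, beta, max_iter = 1000, tol = 1e-4) {
  J <- ncol(f_bg)
  N <- nrow(f_bg)
  p <- colMeans(f_pres)
  lambda <- numeric(J)
  smooth_obj <- function(l) {
    eta <- as.vector(f_bg %*% l)
    logsumexp(eta) - sum(l * p)
  }
  grad_at <- function(l) {
    eta <- as.vector(f_bg %*% l)
    w <- exp(eta - logsumexp(eta))
    as.vector(crossprod(f_bg, w)) - p
  }
  obj <- function(l) smooth_obj(l) + sum(beta * abs(l))

  soft <- function(v, t) sign(v) * pmax(abs(v) - t, 0)
  kkt_ok <- function(g, l) {
    all(abs(g) <= beta + tol) &&
      all(abs(g[l != 0] + beta[l != 0] * sign(l[l != 0])) <= 10 * tol)
  }

  step <- 1
  y <- lambda
  t_acc <- 1
  attrib <- numeric(J)
  cur <- obj(lambda)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    g <- grad_at(y)
    fy <- smooth_obj(y)
    repeat {
      cand <- soft(y - step * g, step * beta)
      d <- cand - y
      if (smooth_obj(cand) <=
          fy + sum(g * d) + sum(d^2) / (2 * step) + 1e-12) break
      step <- step / 2
      if (step < 1e-12) break
    }
    new_obj <- obj(cand)
    if (new_obj > cur) {  # restart momentum from the best point
      y <- lambda; t_acc <- 1
      g <- grad_at(y)
      cand <- soft(y - step * g, step * beta)
      new_obj <- obj(cand)
    }
    dl <- abs(cand - lambda)
    dec <- max(cur - new_obj, 0)
    share <- dl * abs(g)
    if (sum(share) > 0) attrib <- attrib + dec * share / sum(share)
    t_new <- (1 + sqrt(1 + 4 * t_acc^2)) / 2
    y <- cand + ((t_acc - 1) / t_new) * (cand - lambda)
    lambda <- cand
    t_acc <- t_new
    cur <- min(cur, new_obj)
    step <- min(step * 2, 1e6)
    g_l <- grad_at(lambda)
    if (kkt_ok(g_l, lambda)) { converged <- TRUE; break }
  }
  eta_bg <- as.vector(f_bg %*% lambda)
  log_z <- logsumexp(eta_bg)
  w <- exp(eta_bg - log_z)
  entropy <- -sum(ifelse(w > 0, w * log(w), 0))
  nmll <- log_z - sum(lambda * p)
  penalty <- sum(beta * abs(lambda))
  list(
    weights = lambda, beta = beta, converged = converged, n_iter = it,
    log_normalizer = log_z, entropy = entropy,
    loss = nmll + penalty, nmll = nmll,
    training_gain = log(N) - (nmll + penalty),
    presence_means = p,
    model_means = as.vector(crossprod(f_bg, w)),
    gain_attrib = attrib
  )
}

# Map occurrence records to valid cells, sample the background, and
# evaluate features on both; presence cells are appended to the background
# so presence probabilities are always defined.
build_design <- function(occ, stack, features, background_size = 10000,
                         seed = 1L) {
  g <- stack_grid(stack)
  mask <- stack_mask(stack)
  rc <- point_to_cell(g, occ$longitude, occ$latitude)
  cell <- (rc$col - 1L) * g$n_rows + rc$row  # column-major linear index
  ok <- !is.na(cell) & mask[cbind(rc$row, rc$col)]
  pres_cells <- cell[ok]
  if (length(pres_cells) < 1) {
    stop("no presence record falls on a valid grid cell", call. = FALSE)
  }
  valid <- which(mask)
  if (length(valid) <= background_size) {
    bg_cells <- valid
  } else {
    set.seed(seed)
    bg_cells <- sort(sample(valid, background_size))
  }
  bg_cells <- sort(unique(c(bg_cells, pres_cells)))
  x_pres <- stack_matrix(stack, pres_cells)
  x_bg <- stack_matrix(stack, bg_cells)
  list(
    pres_cells = pres_cells, bg_cells = bg_cells,
    x_pres = x_pres, x_bg = x_bg,
    f_pres = eval_features(features, x_pres),
    f_bg = eval_features(features, x_bg)
  )
}

reg_bounds <- function(features, f_pres, rm) {
  m <- nrow(f_pres)
  s_class <- .class_scale[features$defs$class]
  sd_pres <- apply(f_pres, 2, stats::sd)
  if (m < 2) sd_pres[] <- 0
  pmax(rm * s_class * sd_pres / sqrt(m), 1e-4)
}

#' Fit a maximum-entropy suitability model
#'
#' Fits the Gibbs distribution over background cells whose feature
#' expectations match the presence sample's, subject to an L1 penalty: the
#' weights minimize `-(1/m) sum log P(x_i) + sum beta_j |lambda_j|` with
#' `P = exp(lambda . f) / Z` over the background and
#' `beta_j = rm * s_class * sd_j / sqrt(m)` (floored at 1e-4), the standard
#' sample-error regularization bound. The fit is full-batch proximal
#' gradient, checked at convergence against the KKT box
#' `|presence mean - model mean| <= beta_j + tol` for every feature.
#'
#' @param occ Occurrence tibble; records are mapped to grid cells.
#' @param stack An [env_stack()] of predictor layers.
#' @param fc Feature classes to expand (ignored when `features` is given).
#' @param rm Regularization multiplier (> 0).
#' @param features Optional pre-built [expand_features()] result.
#' @param n_knots Threshold/hinge knots per layer.
#' @param background_size Background cells: all valid cells when there are no
#'   more than this many, otherwise a seeded uniform sample of this size.
#'   Presence cells are always appended.
#' @param seed Seed for the background sample.
#' @param max_iter,tol Optimizer budget and KKT tolerance.
#' @return An object of class `maxent_model`.
#' @export
fit_maxent <- function(occ, stack, fc = c("L", "Q"), rm = 1,
                       features = NULL, n_knots = 10,
                       background_size = 10000, seed = 1L,
                       max_iter = 1000, tol = 1e-4) {
  stopifnot(rm > 0)
  if (is.null(features)) features <- expand_features(stack, fc, n_knots)
  design <- build_design(occ, stack, features, background_size, seed)
  if (length(unique(design$pres_cells)) < 2 && nrow(occ) >= 2) {
    # single-cell presence is allowed but worth flagging
    message("all presence records fall in one grid cell")
  }
  beta <- reg_bounds(features, design$f_pres, rm)
  fit <- fit_core(design$f_pres, design$f_bg, beta, max_iter, tol)
  if (!fit$converged) {
    warning("maxent optimizer did not reach the KKT tolerance; result flagged",
            call. = FALSE)
  }
  structure(
    c(fit,
      list(features = features, rm = rm, fc = features$fc,
           design = design, grid = stack_grid(stack),
           layer_names = names(stack), tol = tol)),
    class = "maxent_model"
  )
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(
    "<maxent_model> rm = %g, fc = %s: %d features (%d active), gain %.4f%s\n",
    x$rm, paste(x$fc, collapse = ""), length(x$weights),
    sum(abs(x$weights) > 1e-8), x$training_gain,
    if (x$converged) "" else " [not converged]"
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted maximum-entropy model
#'
#' @param x A `maxent_model`.
#' @param ... Unused.
#' @return One row per feature: `feature`, `class`, `layer`, `weight`,
#'   `reg_bound`, and the presence/model means whose gap the KKT condition
#'   bounds.
#' @export
tidy.maxent_model <- function(x, ...) {
  tibble::tibble(
    feature = x$features$defs$name,
    class = x$features$defs$class,
    layer = x$features$defs$layer1,
    weight = x$weights,
    reg_bound = x$beta,
    presence_mean = x$presence_means,
    model_mean = x$model_means
  )
}

#' @rdname tidy.maxent_model
#' @export
glance.maxent_model <- function(x, ...) {
  tibble::tibble(
    rm = x$rm, fc = paste(x$fc, collapse = ""),
    n_features = length(x$weights),
    n_params = sum(abs(x$weights) > 1e-8),
    training_gain = x$training_gain,
    entropy = x$entropy,
    n_presence = nrow(x$design$f_pres),
    n_background = nrow(x$design$f_bg),
    converged = x$converged
  )
}

# Raw scores (unnormalized log-density) for a matrix of layer values.
model_eta <- function(model, x) {
  as.vector(eval_features(model$features, x) %*% model$weights)
}

#' Project a fitted model onto a stack
#'
#' Raw output is the Gibbs probability normalized over the training
#' background (it sums to 1 there); cumulative output at a cell is 100 times
#' the summed raw value of background cells scoring no higher; logistic
#' output is `r e^H / (1 + r e^H)` with `r` the raw value and `H` the model's
#' background entropy, the conventional 0-1 suitability index (0.5 at
#' typical sites). Projection values are clamped to the training range, so
#' novel conditions score as at the range edge.
#'
#' @param object A `maxent_model`.
#' @param stack Stack to project onto (must carry every layer the model
#'   uses).
#' @param type `"logistic"`, `"raw"`, or `"cumulative"`.
#' @param ... Unused.
#' @return An `enm_raster` suitability map.
#' @export
predict.maxent_model <- function(object, stack = NULL, type = "logistic", ...) {
  type <- match.arg(type, c("logistic", "raw", "cumulative"))
  missing_layers <- setdiff(object$features$norm$layer, names(stack))
  if (length(missing_layers)) {
    stop(sprintf("stack is missing model layer(s): %s",
                 paste(missing_layers, collapse = ", ")), call. = FALSE)
  }
  g <- stack_grid(stack)
  mask <- stack_mask(stack)
  cells <- which(mask)
  eta <- model_eta(object, stack_matrix(stack, cells))
  raw <- exp(eta - object$log_normalizer)
  out <- switch(type,
    raw = raw,
    logistic = {
      reh <- raw * exp(object$entropy)
      reh / (1 + reh)
    },
    cumulative = {
      bg_eta <- as.vector(object$design$f_bg %*% object$weights)
      bg_raw <- exp(bg_eta - object$log_normalizer)
      o <- order(bg_raw)
      cum <- cumsum(bg_raw[o])
      idx <- findInterval(raw, bg_raw[o], left.open = FALSE)
      100 * ifelse(idx > 0, cum[pmin(idx, length(cum))], 0)
    }
  )
  vals <- matrix(NA_real_, g$n_rows, g$n_cols)
  vals[cells] <- out
  enm_raster(vals, g, mask)
}
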