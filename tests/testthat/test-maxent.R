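test_that("feature expansion produces the forced counts", {
  fx <- scenario_fixture()
  st1 <- env_stack(fx$stack["bio_a"])
  expect_equal(nrow(expand_features(st1, "L")$defs), 1)

  f3 <- expand_features(fx$stack, c("L", "Q", "P"))
  expect_equal(nrow(f3$defs), 3 + 3 + 3)  # C(3,2) = 3 products

  # hinge count: 2 directions x n_knots distinct knots per layer
  st2 <- env_stack(fx$stack[c("bio_a", "bio_b")])
  fh <- expand_features(st2, "H", n_knots = 10)
  x <- enmplan:::stack_matrix(st2)
  expected <- sum(vapply(c("bio_a", "bio_b"), function(nm) {
    k <- unique(unname(quantile(x[, nm], 1:10 / 11, type = 7)))
    rng <- range(x[, nm])
    sum(k < rng[2]) + sum(k > rng[1])
  }, numeric(1)))
  expect_equal(nrow(fh$defs), expected)

  # constant layer contributes no T/H features (message, not error)
  g <- grid_spec(5, 5)
  stc <- env_stack(k = enm_raster(matrix(1, 5, 5), g),
                   v = enm_raster(matrix(runif(25), 5, 5), g))
  expect_message(fc <- expand_features(stc, c("T", "H")), "constant")
  expect_false("k" %in% fc$defs$layer1)
})

test_that("all features map into [0, 1] with clamping beyond the range", {
  fx <- scenario_fixture()
  feats <- expand_features(fx$stack, c("L", "Q", "P", "T", "H"), n_knots = 5)
  x <- enmplan:::stack_matrix(fx$stack)
  f <- enmplan:::eval_features(feats, x)
  expect_true(all(f >= 0 & f <= 1))
  # out-of-range values score as at the range edge
  x_out <- x[1:3, , drop = FALSE]
  x_out[1, ] <- apply(x, 2, max) + 100
  x_out[2, ] <- apply(x, 2, min) - 100
  x_edge <- x_out
  x_edge[1, ] <- apply(x, 2, max)
  x_edge[2, ] <- apply(x, 2, min)
  expect_equal(enmplan:::eval_features(feats, x_out),
               enmplan:::eval_features(feats, x_edge))
})

test_that("no-signal and infinite-penalty fits shrink to the uniform model", {
  g <- grid_spec(10, 10)
  set.seed(8)
  st <- env_stack(a = enm_raster(matrix(rnorm(100), 10, 10), g))
  # presences spread over every cell: no signal
  ctr <- cell_center(g, rep(1:10, 10), rep(1:10, each = 10))
  occ_all <- occurrence_set("sp", ctr$x, ctr$y)
  m0 <- fit_maxent(occ_all, st, fc = c("L", "Q"), rm = 1)
  expect_lt(max(abs(m0$weights)), 0.05)
  expect_lt(abs(m0$training_gain), 0.01)

  fx <- scenario_fixture()
  m_inf <- fit_maxent(fx$occ, fx$stack, fc = c("L", "Q"), rm = 1000)
  expect_true(all(abs(m_inf$weights) < 1e-8))
})

test_that("1-feature fit matches a 1-D numerical solution of the penalized problem", {
  # 4-cell world, one binary feature, presence mean 1, background mean 0.5
  g <- grid_spec(2, 2)
  st <- env_stack(a = enm_raster(matrix(c(1, 1, 0, 0), 2, 2), g))
  ctr <- cell_center(g, c(1, 2), c(1, 1))  # the two cells where a = 1
  occ <- occurrence_set("sp", ctr$x, ctr$y)
  feats <- expand_features(st, "L")
  rm <- 0.01
  m <- fit_maxent(occ, st, fc = "L", rm = rm, features = feats, tol = 1e-6)
  # scalar objective over the 6-cell background (4 cells + presences merged):
  design <- m$design
  f_bg <- design$f_bg[, 1]
  beta <- m$beta[1]
  obj <- function(l) log(sum(exp(l * f_bg))) - l * 1 + beta * abs(l)
  opt <- optimize(obj, c(-50, 50), tol = 1e-10)
  expect_equal(unname(m$weights[1]), opt$minimum, tolerance = 1e-3)
})

test_that("the KKT box and raw normalization hold at convergence", {
  fx <- scenario_fixture()
  for (fc in list(c("L", "Q"), c("Q", "T", "H"))) {
    m <- fit_maxent(fx$occ, fx$stack, fc = fc, rm = 1, seed = 1)
    expect_true(m$converged)
    gap <- abs(m$presence_means - m$model_means)
    expect_true(all(gap <= m$beta + 1e-4))
    raw <- exp(as.vector(m$design$f_bg %*% m$weights) - m$log_normalizer)
    expect_equal(sum(raw), 1, tolerance = 1e-9)
  }
})

test_that("training gain is non-increasing in the regularization multiplier", {
  fx <- scenario_fixture()
  gains <- vapply(c(0.5, 1, 2, 4), function(rm) {
    fit_maxent(fx$occ, fx$stack, fc = c("L", "Q"), rm = rm, seed = 1)$training_gain
  }, numeric(1))
  expect_true(all(diff(gains) <= 1e-8))
})

test_that("prediction transforms have their closed forms and shared ranking", {
  fx <- scenario_fixture()
  # uniform model: raw = 1/N, logistic = 0.5
  m_u <- fit_maxent(fx$occ, fx$stack, fc = "L", rm = 1e6)
  raw_u <- predict(m_u, fx$stack, type = "raw")
  n_bg <- nrow(m_u$design$f_bg)
  expect_equal(unique(round(raw_u$values[raw_u$mask], 15)), 1 / n_bg)
  log_u <- predict(m_u, fx$stack, type = "logistic")
  expect_true(all(abs(log_u$values[log_u$mask] - 0.5) < 1e-9))
  expect_equal(m_u$entropy, log(n_bg), tolerance = 1e-6)

  # ranking identical across raw / cumulative / logistic
  m <- fit_maxent(fx$occ, fx$stack, fc = c("L", "Q"), rm = 1, seed = 1)
  r <- predict(m, fx$stack, type = "raw")$values
  c_ <- predict(m, fx$stack, type = "cumulative")$values
  l <- predict(m, fx$stack, type = "logistic")$values
  ok <- !is.na(r)
  expect_equal(rank(r[ok]), rank(l[ok]))
  expect_equal(rank(r[ok], ties.method = "max"),
               rank(c_[ok], ties.method = "max"))

  # missing layer named in the error
  st2 <- env_stack(fx$stack[c("bio_a", "bio_b")])
  expect_error(predict(m, st2), "noise_c")
})

test_that("percent contribution and permutation importance behave as defined", {
  fx <- scenario_fixture()
  st1 <- env_stack(fx$stack["bio_a"])
  m1 <- fit_maxent(fx$occ, st1, fc = c("L", "Q"), rm = 1)
  imp1 <- variable_importance(m1, seed = 1)
  expect_equal(imp1$percent_contribution, 100)
  expect_equal(imp1$permutation_importance, 100)

  m <- fit_maxent(fx$occ, fx$stack, fc = c("L", "Q"), rm = 1, seed = 1)
  imp <- variable_importance(m, seed = 1)
  expect_equal(sum(imp$percent_contribution), 100, tolerance = 0.1)
  expect_equal(sum(imp$permutation_importance), 100, tolerance = 0.1)

  # PI equals an independent manual permutation with the same seed
  x_pres <- m$design$x_pres; x_bg <- m$design$x_bg
  auc_full <- enmplan:::auc_scores(enmplan:::model_eta(m, x_pres),
                                   enmplan:::model_eta(m, x_bg))
  set.seed(1)
  drops <- vapply(m$layer_names, function(nm) {
    comb <- c(x_pres[, nm], x_bg[, nm])
    perm <- sample(comb)
    xp <- x_pres; xb <- x_bg
    xp[, nm] <- perm[seq_len(nrow(xp))]
    xb[, nm] <- perm[-seq_len(nrow(xp))]
    max(0, auc_full - enmplan:::auc_scores(enmplan:::model_eta(m, xp),
                                           enmplan:::model_eta(m, xb)))
  }, numeric(1))
  expect_equal(imp$permutation_importance,
               unname(100 * drops / sum(drops)), tolerance = 1e-9)
})

test_that("a zero-weight appended noise layer gets zero percent contribution", {
  fx <- scenario_fixture()
  m <- fit_maxent(fx$occ, fx$stack, fc = c("L", "Q"), rm = 1, seed = 1)
  imp <- variable_importance(m, seed = 1)
  w <- tidy(m)
  noise_active <- any(abs(w$weight[w$layer == "noise_c"]) > 1e-8)
  if (!noise_active) {
    expect_equal(imp$percent_contribution[imp$layer == "noise_c"], 0,
                 tolerance = 1e-6)
  } else {
    succeed("noise layer carried weight in this fit; attribution non-zero")
  }
})

test_that("jackknife gains are nested-consistent and rank the dominant layer first", {
  fx <- scenario_fixture()
  jk <- jackknife(fx$occ, fx$stack, fc = c("L", "Q"), rm = 1, seed = 1)
  full <- attr(jk, "full_model_gain")
  expect_true(all(jk$without_gain <= full + 1e-6))
  expect_true(all(jk$with_only_gain >= -1e-9))
  informative <- jk$layer[which.max(jk$with_only_gain)]
  expect_true(informative %in% c("bio_a", "bio_b"))

  # single-layer stack: with-only equals the full model
  st1 <- env_stack(fx$stack["bio_a"])
  jk1 <- jackknife(fx$occ, st1, fc = c("L", "Q"), rm = 1, seed = 1)
  expect_equal(jk1$with_only_gain, attr(jk1, "full_model_gain"))
})

test_that("response curves live in (0,1), track monotone suitability, and match prediction", {
  fx <- scenario_fixture()
  rc <- response_curve(fx$occ, fx$stack, "bio_a", fc = c("L", "Q"), rm = 1,
                       seed = 1)
  expect_true(all(rc$logistic > 0 & rc$logistic < 1))
  # the informative layer has positive effect: curve rises overall
  expect_gte(cor(rc$value, rc$logistic, method = "spearman"), 0.9)

  # curve at a background value equals the single-factor model's prediction
  m1 <- attr(rc, "model")
  st1 <- env_stack(fx$stack["bio_a"])
  pred <- predict(m1, st1, type = "logistic")
  cells <- which(pred$mask)[1:5]
  v <- fx$stack[["bio_a"]]$values[cells]
  x <- matrix(v, ncol = 1, dimnames = list(NULL, "bio_a"))
  raw <- exp(enmplan:::model_eta(m1, x) - m1$log_normalizer)
  reh <- raw * exp(m1$entropy)
  expect_equal(unname(reh / (1 + reh)), unname(pred$values[cells]),
               tolerance = 1e-9)
  expect_error(response_curve(fx$occ,
                              env_stack(k = enm_raster(
                                matrix(1, 100, 100), fx$scen$grid)), "k"),
               "constant")
})

test_that("our AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  pos <- rnorm(50, 1); neg <- rnorm(200)
  ours <- enmplan:::auc_scores(pos, neg)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = c(rep(1, 50), rep(0, 200)),
    predictor = c(pos, neg), quiet = TRUE, direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})
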