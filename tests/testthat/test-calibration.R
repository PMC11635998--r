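test_that("candidate enumeration yields the full factorial in canonical order", {
  cands <- enumerate_candidates(0.1, 4, 0.1, c("L", "Q", "P", "T", "H"))
  expect_equal(nrow(cands), 40 * 31)
  expect_equal(nrow(dplyr::distinct(cands)), 1240)
  expect_equal(cands$rm[1], 0.1)
  expect_equal(cands$fc[1], "L")  # lowest bitmask first

  expect_equal(nrow(enumerate_candidates(1, 1, 0.1, "L")), 1)
  c6 <- enumerate_candidates(1, 2, 1, c("L", "Q"))
  expect_equal(nrow(c6), 2 * 3)
  expect_setequal(unique(c6$fc), c("L", "Q", "LQ"))
  expect_error(enumerate_candidates(1, 2, 1, character(0)), "empty")
})

test_that("occurrence splits have the stated sizes and are seed-reproducible", {
  fx <- scenario_fixture()
  occ20 <- fx$occ[1:20, ]
  s0 <- split_occurrences(occ20, 0, seed = 1)
  expect_equal(nrow(s0$train), 20)
  expect_equal(nrow(s0$test), 0)

  occ10 <- fx$occ[1:10, ]
  s <- split_occurrences(occ10, 0.3, seed = 1)
  expect_equal(nrow(s$test), 3)
  expect_equal(nrow(s$train), 7)
  expect_equal(nrow(dplyr::bind_rows(s$train, s$test) |> dplyr::distinct()), 10)

  s1 <- split_occurrences(occ20, 0.3, seed = 5)
  s2 <- split_occurrences(occ20, 0.3, seed = 5)
  expect_identical(s1, s2)
  s3 <- split_occurrences(occ20, 0.3, seed = 6)
  expect_false(identical(s1$test$longitude, s3$test$longitude))
  expect_error(split_occurrences(occ10[1, ], 0.3), "at least 2")
})

test_that("partial ROC separates signal from noise", {
  fx <- scenario_fixture()
  test_occ <- sample_occurrences(fx$truth, 100, seed = 31)
  pred_true <- fx$truth$true_suitability
  pr <- partial_roc(pred_true, test_occ, E = 0.05, n_iter = 200, seed = 1)
  expect_gt(pr$auc_ratio_mean, 1)
  expect_lt(pr$p, 0.05)

  set.seed(12)
  noise_map <- enm_raster(matrix(runif(100 * 100), 100, 100), fx$scen$grid)
  prn <- partial_roc(noise_map, test_occ, E = 0.05, n_iter = 200, seed = 1)
  expect_lt(abs(prn$auc_ratio_mean - 1), 0.1)
  expect_gt(prn$p, 0.05)

  # degenerate bootstrap: a single full-sample iteration is deterministic
  pr1a <- partial_roc(pred_true, test_occ, n_iter = 1, resample_prop = 1,
                      seed = 1)
  pr1b <- partial_roc(pred_true, test_occ, n_iter = 1, resample_prop = 1,
                      seed = 99)
  expect_equal(pr1a$auc_ratio_mean, pr1b$auc_ratio_mean)

  flat <- enm_raster(matrix(1, 100, 100), fx$scen$grid)
  expect_error(partial_roc(flat, test_occ), "constant")
})

test_that("omission rate matches direct counting at the train percentile", {
  fx <- scenario_fixture()
  pred <- fx$truth$true_suitability
  split <- split_occurrences(fx$occ, 0.3, seed = 2)

  tr_scores <- enmplan:::scores_at_points(pred, split$train)
  te_scores <- enmplan:::scores_at_points(pred, split$test)
  thr <- quantile(tr_scores, 0.05, type = 7, names = FALSE)
  expect_equal(omission_rate(pred, split$train, split$test, E = 0.05),
               mean(te_scores < thr))
  # test = train at E = 0.05: OR within one rank unit of 5%
  or_self <- omission_rate(pred, split$train, split$train, E = 0.05)
  expect_lte(abs(or_self - 0.05), 1 / nrow(split$train) + 1e-12)
  expect_error(omission_rate(pred, split$train, split$train[0, ], 0.05),
               "empty")
})

test_that("AICc follows the closed form and its likelihood matches a direct oracle", {
  # closed form: k = 2, n = 10, lnL = -20
  expect_equal(2 * 2 - 2 * (-20) + 2 * 2 * 3 / (10 - 2 - 1),
               45.7142857, tolerance = 1e-6)

  fx <- scenario_fixture()
  m <- fit_maxent(fx$occ, fx$stack, fc = "L", rm = 1, seed = 1)
  a <- aicc(m, stack = fx$stack)
  k <- sum(abs(m$weights) > 1e-8)
  # direct normalization-and-log oracle over the study area
  cells <- which(enmplan:::stack_mask(fx$stack))
  eta <- enmplan:::model_eta(m, enmplan:::stack_matrix(fx$stack, cells))
  p_area <- exp(eta) / sum(exp(eta))
  idx <- match(m$design$pres_cells, cells)
  lnL <- sum(log(p_area[idx]))
  n <- length(idx)
  expect_equal(a, 2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1),
               tolerance = 1e-9)

  # monotone penalty in k at fixed lnL
  aic_k <- function(k, n, lnL) 2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1)
  expect_gt(aic_k(3, 10, -20), aic_k(2, 10, -20))
})

test_that("model selection filters then takes the AICc argmin with stated tie-breaks", {
  mk <- function(rm, fc, p, or, aic, k) {
    tibble::tibble(rm = rm, fc = fc, proc_auc_ratio = 1.5, proc_p = p,
                   omission_rate = or, aicc = aic, n_params = k,
                   delta_aicc = NA_real_)
  }
  metrics <- dplyr::bind_rows(
    mk(1, "L", 0.20, 0.01, 100, 2),   # not significant
    mk(1, "Q", 0.01, 0.20, 90, 2),    # high omission
    mk(1, "LQ", 0.01, 0.01, 105, 3),  # admissible
    mk(2, "L", 0.01, 0.02, 101, 2),   # admissible, lower AICc
    mk(3, "H", 0.01, 0.02, 101, 2)    # tie on AICc and k: lower rm wins
  )
  best <- select_model(metrics)
  expect_equal(c(best$rm, best$fc), c("2", "L"))

  # brute-force filter + argmin oracle on a random table
  set.seed(8)
  tbl <- mk(runif(40, 0.1, 4), sample(c("L", "Q", "H", "LQ"), 40, TRUE),
            runif(40, 0, 0.2), runif(40, 0, 0.2),
            runif(40, 80, 120), sample(1:9, 40, TRUE))
  ok <- tbl$proc_p < 0.05 & tbl$omission_rate <= 0.05
  if (any(ok)) {
    oracle <- tbl[ok, ][order(tbl$aicc[ok], tbl$n_params[ok], tbl$rm[ok],
                              tbl$fc[ok]), ][1, ]
    got <- select_model(tbl)
    expect_equal(got$aicc, oracle$aicc)
    expect_equal(got$rm, oracle$rm)
  }

  allbad <- mk(1, "L", 0.9, 0.9, 100, 2)
  expect_error(select_model(allbad), "no admissible model")
  # fallback: lowest omission among significant candidates
  near <- dplyr::bind_rows(mk(1, "L", 0.01, 0.06, 100, 2),
                           mk(1, "Q", 0.01, 0.08, 90, 2))
  fb <- select_model(near, fallback_min_or = TRUE)
  expect_equal(fb$omission_rate, 0.06)
})

test_that("candidate metrics table evaluates and selects on synthetic data", {
  fx <- scenario_fixture()
  cands <- tidyr::expand_grid(rm = c(0.5, 2), fc = c("LQ", "QTH"))
  metrics <- calibrate_candidates(fx$occ, fx$stack, cands,
                                  n_iter = 50, seed = 3)
  expect_equal(nrow(metrics), 4)
  expect_true(all(metrics$omission_rate >= 0 & metrics$omission_rate <= 1))
  expect_equal(min(metrics$delta_aicc), 0)
  # delta recomputation consistency
  expect_equal(metrics$delta_aicc, metrics$aicc - min(metrics$aicc))
})

test_that("replicate fitting averages maps within replicate bounds", {
  fx <- scenario_fixture()
  rep1 <- replicate_fit(fx$occ, fx$stack, rm = 1, fc = "LQ", n_rep = 1,
                        seed = 4)
  expect_equal(rep1$mean_map$values, rep1$maps[[1]]$values)

  rep3 <- replicate_fit(fx$occ, fx$stack, rm = 1, fc = "LQ", n_rep = 3,
                        seed = 4)
  arr <- sapply(rep3$maps, function(m) m$values[m$mask])
  mm <- rep3$mean_map$values[rep3$mean_map$mask]
  expect_true(all(mm >= apply(arr, 1, min) - 1e-12))
  expect_true(all(mm <= apply(arr, 1, max) + 1e-12))
  expect_true(all(rep3$auc$train_auc >= 0 & rep3$auc$train_auc <= 1))
})

test_that("AUC of perfectly separable data is exactly 1", {
  # presences confined to the high half of a two-level map
  g <- grid_spec(20, 20)
  vals <- matrix(0.1, 20, 20); vals[, 11:20] <- 0.9
  pred <- enm_raster(vals, g)
  occ <- occurrence_set("sp", runif(20, 10.1, 19.9), runif(20, 0.1, 19.9))
  sc <- enmplan:::scores_at_points(pred, occ)
  expect_equal(enmplan:::auc_scores(sc, vals[vals == 0.1]), 1)
})

test_that("AUC is invariant under strictly monotone transforms", {
  fx <- scenario_fixture()
  m <- fit_maxent(fx$occ, fx$stack, fc = c("L", "Q"), rm = 1, seed = 1)
  raw <- predict(m, fx$stack, type = "raw")
  lg <- predict(m, fx$stack, type = "logistic")
  pres_r <- enmplan:::scores_at_points(raw, fx$occ)
  pres_l <- enmplan:::scores_at_points(lg, fx$occ)
  a_r <- enmplan:::auc_scores(pres_r, raw$values[raw$mask])
  a_l <- enmplan:::auc_scores(pres_l, lg$values[lg$mask])
  expect_equal(a_r, a_l, tolerance = 1e-9)
})
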