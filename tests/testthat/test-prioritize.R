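test_that("planning-unit costs follow the capped-sum rule", {
  expect_equal(pu_cost(0, 0), 0)
  expect_equal(pu_cost(1, 0.5), 1)
  expect_equal(pu_cost(0.5, 0.25), 0.75)
  expect_error(pu_cost(-0.1, 0), "\\[0, 1\\]")
})

test_that("feature amounts are probability-weighted zonal areas", {
  g <- grid_spec(4, 4, cell_size = 2)
  lat <- generate_planning_lattice(g, 2, 2, seed = 1)
  # uniform LO = p over each unit: amount = p * unit area
  suit <- enm_raster(matrix(0.25, 4, 4), g)
  amt <- build_feature_matrix(suit, lat$unit_raster,
                              cell_area = cell_area_raster(g))
  expect_equal(amt$amount, rep(0.25 * 4 * 4, 4))  # 4 cells x 4 area units

  zero <- build_feature_matrix(enm_raster(matrix(0, 4, 4), g),
                               lat$unit_raster)
  expect_true(all(zero$amount == 0))

  # random map vs an independent per-unit sum
  set.seed(2)
  v <- matrix(runif(16), 4, 4)
  amt2 <- build_feature_matrix(enm_raster(v, g), lat$unit_raster)
  for (u in 1:4) {
    cells <- lat$unit_raster$values == u
    expect_equal(amt2$amount[amt2$pu == u], sum(v[cells]))
  }
})

test_that("targets scale with total amounts", {
  amt <- tibble::tibble(feature = 1L, pu = 1:4, amount = c(10, 20, 30, 40))
  t30 <- set_targets(amt, prop = 0.3, spf = 1.6)
  expect_equal(t30$target, 30)
  expect_equal(t30$spf, 1.6)
  t100 <- set_targets(amt, prop = 1)
  expect_equal(t100$target, 100)
  expect_error(set_targets(dplyr::mutate(amt, amount = 0), 0.3), "zero total")
})

test_that("objective evaluation matches the stated formula on a 3-unit chain", {
  units <- tibble::tibble(id = 1:3, cost = c(1, 2, 3), area = 1,
                          status = "available")
  bounds <- tibble::tibble(id1 = c(1, 2), id2 = c(2, 3), boundary = c(1, 1))
  amt <- tibble::tibble(feature = 1L, pu = 1:3, amount = c(1, 1, 1))
  feats <- tibble::tibble(id = 1L, name = "f", prop = 2 / 3, target = 2,
                          spf = 1, base_penalty = 3)
  prob <- planning_problem(units, bounds, feats, amt, blm = 1)
  s12 <- objective_value(c(1, 2), prob)
  expect_equal(s12$objective_total, 3 + 1 + 0)
  expect_true(s12$feasible)
  s1 <- objective_value(1, prob)
  expect_equal(s1$objective_total, 1 + 1 + 1 * 3 * (1 / 2))
  expect_false(s1$feasible)
  # components always sum to the total
  expect_equal(sum(s1$components), s1$objective_total, tolerance = 1e-9)

  s0 <- objective_value(integer(0),
                        planning_problem(units, bounds,
                                         dplyr::mutate(feats, target = 0),
                                         amt, blm = 1))
  expect_equal(s0$objective_total, 0)

  noblm <- planning_problem(units, bounds, feats, amt, blm = 0)
  expect_equal(unname(objective_value(c(1, 3), noblm)$components["boundary"]), 0)

  expect_error(objective_value(9, prob), "unknown")
})

test_that("greedy base penalties bracket the exhaustive optimum", {
  # one unit covers the target alone and is cheapest per amount
  units <- tibble::tibble(id = 1:3, cost = c(1, 5, 5), area = 1,
                          status = "available")
  amt <- tibble::tibble(feature = 1L, pu = 1:3, amount = c(10, 1, 1))
  feats <- tibble::tibble(id = 1L, name = "f", prop = 0.5, target = 5, spf = 1)
  prob <- planning_problem(units, tibble::tibble(id1 = integer(0),
                                                 id2 = integer(0),
                                                 boundary = numeric(0)),
                           feats, amt, blm = 0)
  expect_equal(prob$features$base_penalty, 1)

  # identical units: ceil(target / amount) units' worth
  units2 <- tibble::tibble(id = 1:5, cost = 2, area = 1, status = "available")
  amt2 <- tibble::tibble(feature = 1L, pu = 1:5, amount = 3)
  feats2 <- tibble::tibble(id = 1L, name = "f", prop = 0.5, target = 7.5,
                           spf = 1)
  prob2 <- planning_problem(units2, tibble::tibble(id1 = integer(0),
                                                   id2 = integer(0),
                                                   boundary = numeric(0)),
                            feats2, amt2, blm = 0)
  expect_equal(prob2$features$base_penalty, ceiling(7.5 / 3) * 2)

  # random 5-unit instances: greedy within [optimum, 2 x optimum]
  set.seed(4)
  for (k in 1:5) {
    cost <- runif(5, 0.5, 2)
    a <- runif(5, 0.5, 2)
    tgt <- 0.6 * sum(a)
    units3 <- tibble::tibble(id = 1:5, cost = cost, area = 1,
                             status = "available")
    amt3 <- tibble::tibble(feature = 1L, pu = 1:5, amount = a)
    feats3 <- tibble::tibble(id = 1L, name = "f", prop = 0.6, target = tgt,
                             spf = 1)
    prob3 <- planning_problem(units3,
                              tibble::tibble(id1 = integer(0),
                                             id2 = integer(0),
                                             boundary = numeric(0)),
                              feats3, amt3, blm = 0)
    greedy <- prob3$features$base_penalty
    best <- Inf
    for (mask in 1:31) {
      sel <- which(bitwAnd(mask, 2^(0:4)) > 0)
      if (sum(a[sel]) >= tgt) best <- min(best, sum(cost[sel]))
    }
    expect_gte(greedy, best - 1e-9)
    expect_lte(greedy, 2 * best + 1e-9)
  }

  # unreachable target flagged
  featsx <- tibble::tibble(id = 1L, name = "f", prop = 1, target = 100, spf = 1)
  expect_error(planning_problem(units3, tibble::tibble(id1 = integer(0),
                                                       id2 = integer(0),
                                                       boundary = numeric(0)),
                                featsx, amt3, blm = 0), "unreachable")
})

test_that("incremental annealer bookkeeping equals recomputation from scratch", {
  prob <- toy_problem(3, 4)
  for (s in 1:5) {
    sol <- anneal_run(prob, annealing_schedule(n_moves = 500, seed = s))
    full <- objective_value(sol$selected, prob)
    expect_equal(sol$objective_total, full$objective_total, tolerance = 1e-6)
    expect_equal(sol$components, full$components, tolerance = 1e-6)
  }
})

test_that("annealing recovers the exhaustive optimum on a 12-unit instance", {
  prob <- toy_problem(3, 4)
  opt <- exhaustive_optimum(prob)
  hits <- sum(vapply(1:20, function(s) {
    sol <- anneal_run(prob, annealing_schedule(n_moves = 30000, seed = s))
    abs(sol$objective_total - opt$objective) < 1e-9
  }, logical(1)))
  expect_gte(hits, 18)
})

test_that("penalty-dominated problems are driven to feasibility", {
  units <- tibble::tibble(id = 1:6, cost = 0, area = 1, status = "available")
  amt <- tibble::tibble(feature = 1L, pu = 1:6, amount = 1)
  feats <- tibble::tibble(id = 1L, name = "f", prop = 1, target = 6,
                          spf = 100, base_penalty = 10)
  prob <- planning_problem(units, tibble::tibble(id1 = integer(0),
                                                 id2 = integer(0),
                                                 boundary = numeric(0)),
                           feats, amt, blm = 0)
  sol <- anneal_run(prob, annealing_schedule(n_moves = 2000, seed = 1))
  expect_true(sol$feasible)
  expect_equal(sort(sol$selected), 1:6)
})

test_that("objective scaling scales the optimum and preserves the argmin", {
  prob <- toy_problem(3, 4)
  opt <- exhaustive_optimum(prob)
  c_scale <- 3.7
  prob2 <- prob
  prob2$units$cost <- prob$units$cost * c_scale
  prob2$features$base_penalty <- prob$features$base_penalty * c_scale
  prob2$blm <- prob$blm * c_scale
  opt2 <- exhaustive_optimum(prob2)
  expect_equal(opt2$objective, c_scale * opt$objective, tolerance = 1e-9)
  expect_equal(sort(opt2$selected), sort(opt$selected))
})

test_that("ensembles track frequencies, locks, and forced units", {
  prob <- toy_problem(3, 4, spf = 50)
  sch <- annealing_schedule(n_moves = 1500, seed = 7)
  ens <- run_ensemble(prob, sch, n_runs = 10)
  # frequency recount from stored selections
  freq <- sapply(prob$units$id, function(u)
    mean(vapply(ens$selections, function(s) u %in% s, logical(1))))
  expect_equal(ens$selection_frequency$frequency, unname(freq))
  expect_equal(ens$best$objective_total, min(ens$objectives))

  # sole-source unit is always selected; locked-out units never are
  units <- tibble::tibble(id = 1:5, cost = c(0.1, 0.1, 0.1, 0.1, 0.1),
                          area = 1,
                          status = c("available", "available", "available",
                                     "available", "locked_out"))
  amt <- tibble::tibble(feature = 1L, pu = 1:5, amount = c(5, 0, 0, 0, 0))
  feats <- tibble::tibble(id = 1L, name = "f", prop = 0.5, target = 2.5,
                          spf = 100, base_penalty = 5)
  prob2 <- planning_problem(units, tibble::tibble(id1 = integer(0),
                                                  id2 = integer(0),
                                                  boundary = numeric(0)),
                            feats, amt, blm = 0)
  ens2 <- run_ensemble(prob2, annealing_schedule(n_moves = 800, seed = 3),
                       n_runs = 10)
  expect_equal(ens2$selection_frequency$frequency[1], 1)
  expect_equal(ens2$selection_frequency$frequency[5], 0)
})

test_that("sensitivity sweeps move boundary and shortfall the expected way", {
  prob <- toy_problem(4, 4, prop = 0.5, spf = 1, blm = 0.1, seed = 11,
                      amount_seed = 12)
  sens <- sensitivity(prob, blm_grid = c(0, 0.2, 1, 5),
                      spf_grid = c(0.01, 1, 50),
                      schedule = annealing_schedule(n_moves = 2000, seed = 2),
                      n_runs = 3)
  expect_equal(nrow(sens$blm), 4)
  expect_equal(nrow(sens$spf), 3)
  # boundary length non-increasing in BLM up to noise
  expect_lte(cor(sens$blm$blm, sens$blm$best_boundary, method = "spearman"), 0)
  # shortfall non-increasing in SPF
  expect_lte(cor(sens$spf$spf, sens$spf$total_shortfall, method = "spearman"),
             0)
  # single-point grids give one row each
  s1 <- sensitivity(prob, 0.1, 1,
                    schedule = annealing_schedule(n_moves = 500, seed = 2),
                    n_runs = 2)
  expect_equal(c(nrow(s1$blm), nrow(s1$spf)), c(1L, 1L))
})
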