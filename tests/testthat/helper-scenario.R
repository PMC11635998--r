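# Shared fixtures, built in code.

# The default synthetic study: two informative layers + one noise layer on a
# 100 x 100 planar grid, 200 occurrences sampled proportional to suitability.
default_scenario <- function(n = 100, seed = 7) {
  synthetic_scenario(grid = grid_spec(n, n),
                     layer_names = c("bio_a", "bio_b", "noise_c"),
                     smoothness = 6, beta = c(0, 2, 1.5, 0), seed = seed)
}

scenario_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      scen <- default_scenario()
      stack <- generate_env_stack(scen)
      truth <- true_suitability(stack, scen$beta)
      occ <- thin_occurrences(sample_occurrences(truth, 200, seed = 2),
                              scen$grid)
      cache <<- list(scen = scen, stack = stack, truth = truth, occ = occ)
    }
    cache
  }
})

# A deterministic compact-blob world: suitability is a logistic disk around
# (cx, cy), at least `margin` cells from every edge, so pure translations
# keep the suitable region wholly inside the grid.
blob_stack <- function(n = 100, cx = 40, cy = 50) {
  g <- grid_spec(n, n)
  vals <- matrix(0, n, n)
  for (j in seq_len(n)) {
    cc <- cell_center(g, seq_len(n), j)
    vals[, j] <- -((cc$x - cx)^2 + (cc$y - cy)^2)
  }
  env_stack(dist2 = enm_raster(vals, g))
}

# logistic disk truth on a blob stack: suitable iff distance < radius
blob_truth <- function(stack, radius = 12, steep = 0.5) {
  g <- stack_grid(stack)
  d2 <- -stack[["dist2"]]$values
  suit <- 1 / (1 + exp(steep * (sqrt(d2) - radius)))
  truth_raster <- enm_raster(suit, g)
  bin <- enm_raster((suit >= 0.5) * 1, g)
  cells <- which(bin$values == 1)
  rc <- enmplan:::cells_to_rowcol(g, cells)
  ctr <- cell_center(g, rc$row, rc$col)
  structure(list(true_suitability = truth_raster, true_binary = bin,
                 true_centroid = c(x = mean(ctr$x), y = mean(ctr$y))),
            class = "truth_set")
}

# tiny seeded planning instance on an r x c lattice
toy_problem <- function(unit_rows = 3, unit_cols = 4, prop = 0.3, spf = 2,
                        blm = 0.05, seed = 5, amount_seed = 3) {
  g <- grid_spec(unit_rows * 4, unit_cols * 3)
  lat <- generate_planning_lattice(g, unit_rows, unit_cols, seed = seed)
  set.seed(amount_seed)
  amt <- tibble::tibble(feature = 1L, pu = lat$units$id,
                        amount = stats::runif(nrow(lat$units), 0, 2))
  feats <- set_targets(amt, prop = prop, spf = spf)
  planning_problem(lat$units, lat$boundaries, feats, amt, blm = blm)
}

# exhaustive minimum over all 2^n selections (n <= 15)
exhaustive_optimum <- function(problem) {
  n <- nrow(problem$units)
  stopifnot(n <= 15)
  best <- Inf; best_set <- integer(0)
  for (mask in 0:(2^n - 1)) {
    sel <- problem$units$id[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    o <- objective_value(sel, problem)$objective_total
    if (o < best) { best <- o; best_set <- sel }
  }
  list(objective = best, selected = best_set)
}
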