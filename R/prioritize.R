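#' Planning-unit cost from land-cover and protection fractions
#'
#' Cost is the (capped) sum of the fraction of the unit covered by land
#' uses where planting is prohibited and the fraction inside protected
#' areas: `min(1, prohibited + protected)`. Vectorized.
#'
#' @param prohibited_fraction,protected_fraction Fractions in `[0, 1]`.
#' @return Costs in `[0, 1]`.
#' @export
pu_cost <- function(prohibited_fraction, protected_fraction) {
  if (any(prohibited_fraction < 0 | prohibited_fraction > 1) ||
      any(protected_fraction < 0 | protected_fraction > 1)) {
    stop("cost fractions must lie in [0, 1]", call. = FALSE)
  }
  pmin(1, prohibited_fraction + protected_fraction)
}

#' Zonal feature amounts from a suitability map
#'
#' The amount of a feature held by a planning unit is the probability-
#' weighted area `sum(LO * cell_area)` over the unit's valid cells — so a
#' 30% target means 30% of the total probability-weighted habitat.
#'
#' @param suitability Logistic suitability `enm_raster`.
#' @param unit_raster `enm_raster` of planning-unit ids, co-registered.
#' @param cell_area Per-cell area raster or single number.
#' @param feature Feature id (default 1).
#' @return A tibble (`feature`, `pu`, `amount`), one row per unit.
#' @export
build_feature_matrix <- function(suitability, unit_raster, cell_area = 1,
                                 feature = 1L) {
  if (!same_grid(suitability$grid, unit_raster$grid)) {
    stop("suitability and unit rasters are not co-registered", call. = FALSE)
  }
  cells <- which(suitability$mask & unit_raster$mask)
  area <- if (inherits(cell_area, "enm_raster")) {
    cell_area$values[cells]
  } else {
    rep(cell_area, length(cells))
  }
  ids <- sort(unique(unit_raster$values[unit_raster$mask]))
  amt <- tibble::tibble(pu = unit_raster$values[cells],
                        v = suitability$values[cells] * area) |>
    dplyr::group_by(pu) |>
    dplyr::summarise(amount = sum(v), .groups = "drop")
  out <- tibble::tibble(feature = as.integer(feature), pu = as.integer(ids)) |>
    dplyr::left_join(amt, by = "pu") |>
    dplyr::mutate(amount = dplyr::coalesce(amount, 0))
  out
}

#' Feature targets from amounts
#'
#' `target = prop * sum(amount)` per feature, with the species penalty
#' factor attached.
#'
#' @param amounts Tibble (`feature`, `pu`, `amount`).
#' @param prop Target proportion in (0, 1].
#' @param spf Species penalty factor.
#' @param name Feature names (recycled).
#' @return A tibble (`id`, `name`, `prop`, `target`, `spf`).
#' @export
set_targets <- function(amounts, prop = 0.3, spf = 1.6, name = "feature") {
  stopifnot(prop > 0, prop <= 1)
  tot <- amounts |>
    dplyr::group_by(feature) |>
    dplyr::summarise(total = sum(amount), .groups = "drop")
  if (any(tot$total <= 0)) {
    stop("feature with zero total amount", call. = FALSE)
  }
  tibble::tibble(id = tot$feature, name = rep_len(name, nrow(tot)),
                 prop = prop, target = prop * tot$total, spf = spf)
}

#' Assemble a validated planning problem
#'
#' The minimum-set problem: choose planning units minimizing
#' `cost + BLM * boundary + sum(SPF * base_penalty * shortfall/target) +
#' cost-threshold penalty`, where `boundary` counts shared edges between
#' selected and unselected units.
#'
#' @param units Tibble with `id`, `cost` (>= 0), `area`, `status`
#'   (`available` / `locked_in` / `locked_out`).
#' @param boundaries Tibble (`id1`, `id2`, `boundary`) with `id1 < id2`,
#'   each pair once, ids existing in `units`.
#' @param features Tibble from [set_targets()]; a `base_penalty` column is
#'   computed by [greedy_base_penalty()] when absent.
#' @param amounts Tibble (`feature`, `pu`, `amount`), amounts >= 0.
#' @param blm Boundary length modifier (>= 0).
#' @param cost_threshold Optional list `list(threshold =, weight =)`
#'   activating the cost-threshold penalty; `NULL` (default) disables it.
#' @return An object of class `planning_problem`.
#' @export
planning_problem <- function(units, boundaries, features, amounts,
                             blm = 0, cost_threshold = NULL) {
  if (anyDuplicated(units$id)) stop("duplicate planning-unit id", call. = FALSE)
  if (any(units$cost < 0)) stop("negative planning-unit cost", call. = FALSE)
  if (!all(units$status %in% c("available", "locked_in", "locked_out"))) {
    stop("unit status must be available / locked_in / locked_out", call. = FALSE)
  }
  if (nrow(boundaries)) {
    if (!all(boundaries$id1 %in% units$id) ||
        !all(boundaries$id2 %in% units$id)) {
      stop("boundary references unknown planning-unit id", call. = FALSE)
    }
    if (any(boundaries$id1 >= boundaries$id2)) {
      stop("boundaries must have id1 < id2", call. = FALSE)
    }
    if (anyDuplicated(paste(boundaries$id1, boundaries$id2))) {
      stop("duplicate boundary pair", call. = FALSE)
    }
  }
  if (any(amounts$amount < 0)) stop("negative feature amount", call. = FALSE)
  if (any(features$target < 0)) stop("negative target", call. = FALSE)
  stopifnot(blm >= 0)
  if (!"area" %in% names(units)) units$area <- 1
  problem <- structure(
    list(units = units, boundaries = boundaries, features = features,
         amounts = amounts, blm = blm, cost_threshold = cost_threshold),
    class = "planning_problem"
  )
  if (!"base_penalty" %in% names(features)) {
    problem$features$base_penalty <- 0
    problem$features$base_penalty <- vapply(
      features$id, function(f) greedy_base_penalty(problem, f), numeric(1))
  }
  problem
}

#' @export
print.planning_problem <- function(x, ...) {
  cat(sprintf(
    "<planning_problem> %d units, %d boundaries, %d feature(s), blm = %g\n",
    nrow(x$units), nrow(x$boundaries), nrow(x$features), x$blm))
  invisible(x)
}

# dense internal representation used by the objective and the annealer
problem_internals <- function(problem) {
  ids <- problem$units$id
  n <- length(ids)
  idx_of <- stats::setNames(seq_len(n), ids)
  fids <- problem$features$id
  amat <- matrix(0, length(fids), n,
                 dimnames = list(as.character(fids), NULL))
  if (nrow(problem$amounts)) {
    amat[cbind(match(problem$amounts$feature, fids),
               idx_of[as.character(problem$amounts$pu)])] <-
      problem$amounts$amount
  }
  nb <- problem$boundaries
  edges_i <- idx_of[as.character(nb$id1)]
  edges_j <- idx_of[as.character(nb$id2)]
  adj <- vector("list", n)
  for (e in seq_along(edges_i)) {
    i <- edges_i[e]; j <- edges_j[e]
    adj[[i]] <- rbind(adj[[i]], c(j, nb$boundary[e]))
    adj[[j]] <- rbind(adj[[j]], c(i, nb$boundary[e]))
  }
  list(ids = ids, n = n, idx_of = idx_of, cost = problem$units$cost,
       status = problem$units$status, amat = amat,
       targets = problem$features$target, spf = problem$features$spf,
       base_penalty = problem$features$base_penalty, adj = adj,
       blm = problem$blm, cost_threshold = problem$cost_threshold)
}

penalty_component <- function(held, internals) {
  shortfall <- pmax(0, internals$targets - held)
  safe_t <- ifelse(internals$targets > 0, internals$targets, 1)
  sum(internals$spf * internals$base_penalty * shortfall / safe_t)
}

threshold_component <- function(cost_sum, internals) {
  ct <- internals$cost_threshold
  if (is.null(ct)) return(0)
  ct$weight * max(0, cost_sum - ct$threshold)
}

#' Evaluate the planning objective for a selection
#'
#' @param selected Vector of selected planning-unit ids.
#' @param problem A [planning_problem()]; the selection must honour its
#'   locked statuses.
#' @return An object of class `planning_solution`: the selection, the
#'   objective components (`cost`, `boundary`, `penalty`,
#'   `cost_threshold`) and their sum `objective_total`, per-feature `held`
#'   amounts and `shortfall`s, and a `feasible` flag.
#' @export
objective_value <- function(selected, problem) {
  internals <- problem_internals(problem)
  unknown <- setdiff(selected, internals$ids)
  if (length(unknown)) {
    stop(sprintf("unknown planning-unit id: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  sel <- logical(internals$n)
  sel[internals$idx_of[as.character(selected)]] <- TRUE
  if (any(internals$status == "locked_in" & !sel)) {
    stop("selection omits a locked-in unit", call. = FALSE)
  }
  if (any(internals$status == "locked_out" & sel)) {
    stop("selection includes a locked-out unit", call. = FALSE)
  }
  solution_from_state(sel, internals, problem)
}

solution_from_state <- function(sel, internals, problem) {
  cost_sum <- sum(internals$cost[sel])
  boundary <- 0
  for (i in which(sel)) {
    a <- internals$adj[[i]]
    if (!is.null(a)) boundary <- boundary + sum(a[!sel[a[, 1]], 2])
  }
  held <- as.vector(internals$amat %*% sel)
  shortfall <- pmax(0, internals$targets - held)
  pen <- penalty_component(held, internals)
  thr <- threshold_component(cost_sum, internals)
  comp <- c(cost = cost_sum, boundary = internals$blm * boundary,
            penalty = pen, cost_threshold = thr)
  structure(
    list(selected = sort(internals$ids[sel]),
         objective_total = sum(comp), components = comp,
         held = stats::setNames(held, problem$features$id),
         shortfall = stats::setNames(shortfall, problem$features$id),
         feasible = all(shortfall <= 1e-9)),
    class = "planning_solution"
  )
}

#' @export
print.planning_solution <- function(x, ...) {
  cat(sprintf(
    "<planning_solution> %d units, objective %.4f (cost %.3f + boundary %.3f + penalty %.3f + threshold %.3f)%s\n",
    length(x$selected), x$objective_total, x$components["cost"],
    x$components["boundary"], x$components["penalty"],
    x$components["cost_threshold"],
    if (x$feasible) ", feasible" else ", INFEASIBLE"))
  invisible(x)
}

#' Greedy scale for the shortfall penalty
#'
#' The penalty coefficient of a feature is the cost (plus weighted exposed
#' boundary) of the set built by greedily adding units in increasing
#' cost-per-amount order until the feature's target is met — an upper-bound
#' estimate of what meeting the target costs, so an unmet target is never
#' cheaper than meeting it.
#'
#' @param problem A [planning_problem()] (a `base_penalty` column is not
#'   required).
#' @param feature Feature id.
#' @return The base penalty; errors if the target is unreachable.
#' @export
greedy_base_penalty <- function(problem, feature) {
  internals <- problem_internals(problem)
  k <- match(feature, problem$features$id)
  target <- problem$features$target[k]
  if (target <= 0) return(0)
  amounts <- internals$amat[k, ]
  if (sum(amounts) < target) {
    stop(sprintf("feature %s target unreachable (total %.4g < target %.4g)",
                 feature, sum(amounts), target), call. = FALSE)
  }
  ratio <- ifelse(amounts > 0, internals$cost / amounts, Inf)
  ord <- order(ratio, internals$cost)
  sel <- logical(internals$n)
  held <- 0
  for (i in ord) {
    if (held >= target) break
    if (amounts[i] <= 0) break
    sel[i] <- TRUE
    held <- held + amounts[i]
  }
  cost_sum <- sum(internals$cost[sel])
  boundary <- 0
  for (i in which(sel)) {
    a <- internals$adj[[i]]
    if (!is.null(a)) boundary <- boundary + sum(a[!sel[a[, 1]], 2])
  }
  cost_sum + internals$blm * boundary
}

#' Annealing schedule
#'
#' @param n_moves Moves per run (default 100000).
#' @param t_initial Initial temperature, or `NULL` for the adaptive default:
#'   the 80th percentile of absolute objective deltas over 1000 probe moves,
#'   so early acceptance is roughly 80%.
#' @param t_final_frac Final temperature as a fraction of the initial
#'   (geometric cooling).
#' @param seed Integer seed.
#' @return An object of class `annealing_schedule`.
#' @export
annealing_schedule <- function(n_moves = 100000, t_initial = NULL,
                               t_final_frac = 1e-4, seed = 1L) {
  stopifnot(n_moves >= 1, t_final_frac > 0, t_final_frac < 1)
  structure(list(n_moves = as.integer(n_moves), t_initial = t_initial,
                 t_final_frac = t_final_frac, seed = as.integer(seed)),
            class = "annealing_schedule")
}

# flip delta for unit i given current state; used by probe and anneal loops
flip_delta <- function(i, sel, held, cost_sum, internals) {
  s <- if (sel[i]) -1 else 1
  d_cost <- s * internals$cost[i]
  d_bound <- 0
  a <- internals$adj[[i]]
  if (!is.null(a)) {
    nb_sel <- sel[a[, 1]]
    # edges to unselected neighbours appear/disappear; edges to selected do the opposite
    d_bound <- s * (sum(a[!nb_sel, 2]) - sum(a[nb_sel, 2]))
  }
  new_held <- held + s * internals$amat[, i]
  d_pen <- penalty_component(new_held, internals) -
    penalty_component(held, internals)
  d_thr <- threshold_component(cost_sum + d_cost, internals) -
    threshold_component(cost_sum, internals)
  list(delta = d_cost + internals$blm * d_bound + d_pen + d_thr,
       d_cost = d_cost, d_bound = internals$blm * d_bound,
       new_held = new_held)
}

#' One simulated-annealing run
#'
#' Starts from a random selection honouring locked statuses, then performs
#' `n_moves` single-unit flips, accepting improvements always and
#' deteriorations with probability `exp(-delta / T)` under geometric
#' cooling. Objective bookkeeping is incremental; the best selection seen is
#' kept and, by default, finished with an iterative-improvement sweep
#' (deterministically flipping any unit that lowers the objective until no
#' single flip helps), the classic post-annealing polish of minimum-set
#' solvers. Deterministic under the schedule seed.
#'
#' @param problem A [planning_problem()].
#' @param schedule An [annealing_schedule()].
#' @param polish Run the iterative-improvement sweep on the best-seen
#'   selection (default `TRUE`).
#' @return The best-seen `planning_solution`.
#' @export
anneal_run <- function(problem, schedule = annealing_schedule(),
                       polish = TRUE) {
  internals <- problem_internals(problem)
  avail <- which(internals$status == "available")
  if (!length(avail)) stop("no available planning units", call. = FALSE)
  set.seed(schedule$seed)
  sel <- internals$status == "locked_in"
  sel[avail] <- stats::runif(length(avail)) < 0.5
  held <- as.vector(internals$amat %*% sel)
  cost_sum <- sum(internals$cost[sel])

  cur <- solution_from_state(sel, internals, problem)$objective_total
  best_obj <- cur
  best_sel <- sel

  t0 <- schedule$t_initial
  if (is.null(t0)) {
    probes <- sample(avail, min(1000, 10 * length(avail)), replace = TRUE)
    deltas <- abs(vapply(probes, function(i)
      flip_delta(i, sel, held, cost_sum, internals)$delta, numeric(1)))
    t0 <- max(stats::quantile(deltas, 0.8, names = FALSE), 1e-8)
  }
  alpha <- schedule$t_final_frac^(1 / schedule$n_moves)
  temp <- t0
  picks <- sample(avail, schedule$n_moves, replace = TRUE)
  us <- stats::runif(schedule$n_moves)
  for (mv in seq_len(schedule$n_moves)) {
    i <- picks[mv]
    fd <- flip_delta(i, sel, held, cost_sum, internals)
    if (fd$delta < 0 || us[mv] < exp(-fd$delta / temp)) {
      sel[i] <- !sel[i]
      held <- fd$new_held
      cost_sum <- cost_sum + fd$d_cost
      cur <- cur + fd$delta
      if (cur < best_obj - 1e-12) {
        best_obj <- cur
        best_sel <- sel
      }
    }
    temp <- temp * alpha
  }
  if (polish) {
    sel <- best_sel
    held <- as.vector(internals$amat %*% sel)
    cost_sum <- sum(internals$cost[sel])
    repeat {
      improved <- FALSE
      for (i in avail) {
        fd <- flip_delta(i, sel, held, cost_sum, internals)
        if (fd$delta < -1e-12) {
          sel[i] <- !sel[i]
          held <- fd$new_held
          cost_sum <- cost_sum + fd$d_cost
          improved <- TRUE
        }
      }
      if (!improved) break
    }
    best_sel <- sel
  }
  solution_from_state(best_sel, internals, problem)
}

#' Ensemble of annealing runs
#'
#' Independent seeded runs give the per-unit selection frequency (the usual
#' irre-placeability surrogate) and the best solution over runs.
#'
#' @param problem A [planning_problem()].
#' @param schedule Base [annealing_schedule()]; run r uses `seed + r`.
#' @param n_runs Number of runs (the conventional ensemble is 100).
#' @return An object of class `run_ensemble`: `best` solution,
#'   `selection_frequency` tibble (`id`, `frequency`), and the per-run
#'   objective values.
#' @export
run_ensemble <- function(problem, schedule = annealing_schedule(),
                         n_runs = 100) {
  stopifnot(n_runs >= 1)
  ids <- problem$units$id
  counts <- stats::setNames(numeric(length(ids)), ids)
  best <- NULL
  objectives <- numeric(n_runs)
  selections <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    sch <- schedule
    sch$seed <- schedule$seed + r
    sol <- anneal_run(problem, sch)
    objectives[r] <- sol$objective_total
    selections[[r]] <- sol$selected
    counts[as.character(sol$selected)] <-
      counts[as.character(sol$selected)] + 1
    if (is.null(best) || sol$objective_total < best$objective_total) {
      best <- sol
    }
  }
  structure(
    list(best = best,
         selection_frequency = tibble::tibble(id = ids,
                                              frequency = unname(counts) / n_runs),
         objectives = objectives, selections = selections,
         n_runs = n_runs),
    class = "run_ensemble"
  )
}

#' @export
print.run_ensemble <- function(x, ...) {
  cat(sprintf("<run_ensemble> %d runs, best objective %.4f (%d units)\n",
              x$n_runs, x$best$objective_total, length(x$best$selected)))
  invisible(x)
}

#' Sensitivity curves for BLM and SPF
#'
#' Sweeps the boundary length modifier (species penalty factor fixed) and
#' the species penalty factor (modifier fixed), reporting the best
#' solution's cost and boundary per BLM value and the feasibility rate and
#' summed shortfall per SPF value — the curves used to pick the two knobs.
#'
#' @param problem A [planning_problem()].
#' @param blm_grid,spf_grid Non-empty value grids.
#' @param schedule An [annealing_schedule()].
#' @param n_runs Runs per grid point.
#' @return A list of tibbles `blm` (`blm`, `best_cost`, `best_boundary`,
#'   `best_objective`) and `spf` (`spf`, `feasibility_rate`,
#'   `total_shortfall`).
#' @export
sensitivity <- function(problem, blm_grid, spf_grid,
                        schedule = annealing_schedule(), n_runs = 5) {
  stopifnot(length(blm_grid) > 0, length(spf_grid) > 0)
  blm_tab <- purrr::map_dfr(blm_grid, function(b) {
    p <- problem
    p$blm <- b
    p$features$base_penalty <- vapply(
      p$features$id, function(f) greedy_base_penalty(p, f), numeric(1))
    ens <- run_ensemble(p, schedule, n_runs)
    tibble::tibble(blm = b,
                   best_cost = unname(ens$best$components["cost"]),
                   best_boundary = unname(ens$best$components["boundary"] /
                                            max(b, 1e-12)),
                   best_objective = ens$best$objective_total)
  })
  spf_tab <- purrr::map_dfr(spf_grid, function(s) {
    p <- problem
    p$features$spf <- s
    ens <- run_ensemble(p, schedule, n_runs)
    feas <- vapply(seq_len(ens$n_runs), function(r) {
      objective_value(ens$selections[[r]], p)$feasible
    }, logical(1))
    tibble::tibble(spf = s,
                   feasibility_rate = mean(feas),
                   total_shortfall = sum(ens$best$shortfall))
  })
  list(blm = blm_tab, spf = spf_tab)
}
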