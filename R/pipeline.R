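#' Default pipeline configuration
#'
#' A flat, human-readable configuration covering every stage of the
#' analysis: synthetic-scenario simulation, occurrence thinning, variable
#' selection, candidate calibration, final fitting and projection,
#' three-class mapping, scenario change and centroid tracking, and
#' minimum-set prioritization. The defaults describe the package's standard
#' synthetic study (two informative layers plus one noise layer on a
#' 100 x 100 grid) at sizes that run in seconds.
#'
#' @param seed Global seed; stage s uses `seed + s` so stage randomness is
#'   decoupled.
#' @param out_dir Output directory for stage artifacts.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("enmplan_run_")) {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    stages = c("simulate", "thin", "select_vars", "calibrate", "fit",
               "classify", "change", "centroid", "prioritize"),
    sim_rows = 100, sim_cols = 100, sim_layers = 3,
    sim_smoothness = 6, sim_beta = c(0, 2, 1.5, 0), sim_n_occ = 200,
    shift_cells = c(0, 10),
    r_threshold = 0.85, pc_threshold = 1,
    rm_grid = c(0.5, 1, 2), fc_grid = c("LQ", "QTH", "H"),
    test_fraction = 0.3, proc_iters = 100, n_reps = 3,
    presence_rule = "suitable_or_sub",
    unit_rows = 10, unit_cols = 10,
    prop = 0.3, blm = 1.6, spf = 1.6, runs = 10, moves = 2000
  ), class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Range-checks every parameter and returns all problems at once rather
#' than failing at the first.
#'
#' @param config A [pipeline_config()] (possibly edited).
#' @return The config, invisibly, when valid; otherwise an error listing
#'   every violated field.
#' @export
validate_config <- function(config) {
  errs <- character(0)
  chk <- function(ok, msg) if (!ok) errs <<- c(errs, msg)
  chk(is.numeric(config$seed), "seed must be numeric")
  chk(config$sim_rows >= 10 && config$sim_cols >= 10,
      "sim_rows/sim_cols must be >= 10")
  chk(config$sim_n_occ >= 5, "sim_n_occ must be >= 5")
  chk(config$r_threshold > 0 && config$r_threshold <= 1,
      "r_threshold must be in (0, 1]")
  chk(config$pc_threshold >= 0, "pc_threshold must be >= 0")
  chk(all(config$rm_grid > 0), "rm_grid values must be > 0")
  chk(config$test_fraction >= 0 && config$test_fraction < 1,
      "test_fraction must be in [0, 1)")
  chk(config$prop > 0 && config$prop <= 1, "prop must be in (0, 1]")
  chk(config$blm >= 0, "blm must be >= 0")
  chk(config$spf > 0, "spf must be > 0")
  chk(config$runs >= 1, "runs must be >= 1")
  chk(config$moves >= 1, "moves must be >= 1")
  chk(all(config$stages %in% c("simulate", "thin", "select_vars", "calibrate",
                               "fit", "classify", "change", "centroid",
                               "prioritize")),
      "unknown stage name in `stages`")
  if (length(errs)) {
    stop(paste0("invalid configuration:\n  - ",
                paste(errs, collapse = "\n  - ")), call. = FALSE)
  }
  invisible(config)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file of flat keys as in [pipeline_config()].
#' @return A validated `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  config <- pipeline_config()
  for (nm in names(raw)) config[[nm]] <- raw[[nm]]
  validate_config(config)
  config
}

stage_seed <- function(config, stage) {
  config$seed + match(stage, c("simulate", "thin", "select_vars", "calibrate",
                               "fit", "classify", "change", "centroid",
                               "prioritize"))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order on the configured synthetic
#' scenario, writing stage artifacts under `config$out_dir` and returning a
#' manifest of outputs with content hashes; identical config and seed give
#' identical hashes for every deterministic stage. Stage dependencies are
#' checked up front (e.g. `classify` needs `fit`).
#'
#' @param config A validated [pipeline_config()].
#' @return A list of class `run_manifest`: per-stage result objects,
#'   `files` tibble (`stage`, `path`, `md5`), and the config used.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  validate_config(config)
  stages <- config$stages
  deps <- list(thin = "simulate", select_vars = "thin", calibrate = "select_vars",
               fit = "calibrate", classify = "fit", change = "classify",
               centroid = "change", prioritize = "classify")
  for (s in stages) {
    need <- deps[[s]]
    if (!is.null(need) && !need %in% stages) {
      stop(sprintf("stage '%s' requires stage '%s'", s, need), call. = FALSE)
    }
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  files <- list()
  emit <- function(stage, path) {
    files[[length(files) + 1]] <<- tibble::tibble(
      stage = stage, path = path, md5 = unname(tools::md5sum(path)))
  }
  log_stage <- function(stage, what) {
    message(sprintf("[%s] %s", stage, what))
  }

  if ("simulate" %in% stages) {
    log_stage("simulate", sprintf("%d x %d grid, %d layers, %d occurrences",
                                  config$sim_rows, config$sim_cols,
                                  config$sim_layers, config$sim_n_occ))
    grid <- grid_spec(config$sim_rows, config$sim_cols)
    scen <- synthetic_scenario(
      grid = grid,
      layer_names = paste0("env_", seq_len(config$sim_layers)),
      smoothness = config$sim_smoothness,
      beta = config$sim_beta, seed = stage_seed(config, "simulate"))
    stack <- generate_env_stack(scen)
    truth <- true_suitability(stack, scen$beta)
    occ <- sample_occurrences(truth, config$sim_n_occ,
                              seed = stage_seed(config, "simulate"))
    future <- shift_scenario(stack, config$shift_cells)
    for (nm in names(stack)) {
      p <- file.path(config$out_dir, paste0(nm, ".asc"))
      write_asc(stack[[nm]], p); emit("simulate", p)
    }
    p <- file.path(config$out_dir, "occurrences.csv")
    write_occurrences(occ, p); emit("simulate", p)
    res$simulate <- list(scenario = scen, stack = stack, truth = truth,
                         occ = occ, future = future)
  }
  if ("thin" %in% stages) {
    thin <- thin_occurrences(res$simulate$occ, stack_grid(res$simulate$stack))
    log_stage("thin", sprintf("%d -> %d records", nrow(res$simulate$occ),
                              nrow(thin)))
    p <- file.path(config$out_dir, "occurrences_thinned.csv")
    write_occurrences(thin, p); emit("thin", p)
    res$thin <- thin
  }
  if ("select_vars" %in% stages) {
    sel_r <- pearson_filter(res$simulate$stack,
                            r_threshold = config$r_threshold)
    kept <- sel_r$layer[sel_r$kept]
    sub <- env_stack(res$simulate$stack[kept])
    sel_c <- contribution_prescreen(res$thin, sub,
                                    pc_threshold = config$pc_threshold,
                                    seed = stage_seed(config, "select_vars"))
    kept2 <- sel_c$layer[sel_c$kept]
    log_stage("select_vars", paste("kept:", paste(kept2, collapse = ", ")))
    p <- file.path(config$out_dir, "variable_selection.csv")
    utils::write.csv(dplyr::left_join(
      tibble::as_tibble(sel_r), tibble::as_tibble(sel_c),
      by = "layer", suffix = c("_pearson", "_contribution")), p,
      row.names = FALSE)
    emit("select_vars", p)
    res$select_vars <- list(pearson = sel_r, contribution = sel_c,
                            stack = env_stack(res$simulate$stack[kept2]))
  }
  if ("calibrate" %in% stages) {
    cands <- tidyr::expand_grid(rm = config$rm_grid, fc = config$fc_grid)
    metrics <- calibrate_candidates(
      res$thin, res$select_vars$stack, cands,
      test_fraction = config$test_fraction, n_iter = config$proc_iters,
      seed = stage_seed(config, "calibrate"))
    best <- select_model(metrics, fallback_min_or = TRUE)
    log_stage("calibrate", sprintf("selected rm = %g, fc = %s", best$rm,
                                   best$fc))
    p <- file.path(config$out_dir, "candidate_metrics.csv")
    utils::write.csv(metrics, p, row.names = FALSE); emit("calibrate", p)
    res$calibrate <- list(metrics = metrics, best = best)
  }
  if ("fit" %in% stages) {
    rep <- replicate_fit(res$thin, res$select_vars$stack,
                         rm = res$calibrate$best$rm,
                         fc = res$calibrate$best$fc,
                         n_rep = config$n_reps,
                         test_fraction = config$test_fraction,
                         seed = stage_seed(config, "fit"))
    log_stage("fit", sprintf("mean training AUC %.3f", rep$auc_mean))
    p <- file.path(config$out_dir, "suitability_current.asc")
    write_asc(rep$mean_map, p); emit("fit", p)
    # project the final-settings model onto the shifted scenario
    model <- fit_maxent(res$thin, res$select_vars$stack,
                        fc = strsplit(res$calibrate$best$fc, "")[[1]],
                        rm = res$calibrate$best$rm,
                        seed = stage_seed(config, "fit"))
    future_stack <- env_stack(res$simulate$future[names(res$select_vars$stack)])
    future_map <- predict(model, future_stack, type = "logistic")
    p2 <- file.path(config$out_dir, "suitability_future.asc")
    write_asc(future_map, p2); emit("fit", p2)
    res$fit <- list(replicates = rep, model = model,
                    current_map = rep$mean_map, future_map = future_map)
  }
  if ("classify" %in% stages) {
    model <- res$fit$model
    stack <- res$select_vars$stack
    pred_log <- res$fit$current_map
    pred_cum <- predict(model, stack, type = "cumulative")
    pres_scores <- scores_at_points(pred_log, res$thin)
    bg <- pred_log$values[pred_log$mask]
    ths <- threshold_set(
      tpt = balance_threshold(pres_scores, bg,
                              pred_cum$values[pred_cum$mask]),
      mtss = mtss_threshold(pres_scores, bg))
    cls_now <- classify(pred_log, ths)
    cls_future <- classify(res$fit$future_map, ths)
    log_stage("classify", sprintf("tpt = %.4f, mtss = %.4f", ths$tpt,
                                  ths$mtss))
    p <- file.path(config$out_dir, "classified_current.asc")
    write_asc(cls_now, p, digits = 0); emit("classify", p)
    res$classify <- list(thresholds = ths, current = cls_now,
                         future = cls_future)
  }
  if ("change" %in% stages) {
    cmap <- change_map(res$classify$current, res$classify$future,
                       presence_rule = config$presence_rule)
    stats <- change_stats(cmap)
    log_stage("change", sprintf("expansion %.1f%%, stability %.1f%%",
                                stats$rate_pct[stats$category == "expansion"],
                                stats$rate_pct[stats$category ==
                                                 "no_change_present"]))
    p <- file.path(config$out_dir, "change_stats.csv")
    utils::write.csv(stats, p, row.names = FALSE); emit("change", p)
    res$change <- list(map = cmap, stats = stats)
  }
  if ("centroid" %in% stages) {
    track <- centroid_track(list(current = res$classify$current,
                                 future = res$classify$future),
                            class_rule = "suitable_or_sub")
    log_stage("centroid", sprintf("displacement %.2f map units",
                                  track$dist_from_base[2]))
    p <- file.path(config$out_dir, "centroid_track.csv")
    utils::write.csv(track, p, row.names = FALSE); emit("centroid", p)
    res$centroid <- track
  }
  if ("prioritize" %in% stages) {
    lattice <- generate_planning_lattice(
      stack_grid(res$simulate$stack), config$unit_rows, config$unit_cols,
      seed = stage_seed(config, "prioritize"))
    amounts <- build_feature_matrix(res$fit$current_map,
                                    lattice$unit_raster)
    feats <- set_targets(amounts, prop = config$prop, spf = config$spf)
    problem <- planning_problem(lattice$units, lattice$boundaries, feats,
                                amounts, blm = config$blm)
    ens <- run_ensemble(problem,
                        annealing_schedule(
                          n_moves = config$moves,
                          seed = stage_seed(config, "prioritize")),
                        n_runs = config$runs)
    log_stage("prioritize", sprintf("best objective %.3f, %d units selected",
                                    ens$best$objective_total,
                                    length(ens$best$selected)))
    write_marxan(problem, file.path(config$out_dir, "marxan"))
    for (f in c("pu.dat", "spec.dat", "puvspr.dat", "bound.dat")) {
      emit("prioritize", file.path(config$out_dir, "marxan", f))
    }
    p <- file.path(config$out_dir, "selection_frequency.csv")
    utils::write.csv(ens$selection_frequency, p, row.names = FALSE)
    emit("prioritize", p)
    res$prioritize <- list(problem = problem, ensemble = ens)
  }
  structure(list(results = res,
                 files = dplyr::bind_rows(files),
                 config = config),
            class = "run_manifest")
}
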