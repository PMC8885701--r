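#' Configure an end-to-end experiment
#'
#' The experiment follows a two-stage design. Stage 1 runs the pooled-ERM
#' grid over model specs and early-stopping criteria and selects by overall
#' validation loss. Stage 2 runs the alternative approaches with the
#' model-class hyperparameters fixed to the stage-1 choice: balanced-sampling
#' ERM, stratified ERM, and the DRO variants over a grid of eta (and C) and
#' sampling rules, each selected by a worst-case criterion. Stage 3 scores
#' the selected replicate models on the held-out test set and produces
#' stratified-bootstrap reports, absolute and relative to pooled ERM.
#'
#' @param scenario A [scenario_spec()] (a cohort is generated) or `NULL`
#'   when `cohort_path` is given.
#' @param cohort_path Optional CSV path read via [read_cohort()].
#' @param schema Schema list for [read_cohort()].
#' @param n Cohort size when generating from a scenario.
#' @param approaches Character subset of `c("balanced_erm", "stratified_erm",
#'   "dro_unadjusted", "dro_reciprocal_size", "dro_proportional_size",
#'   "dro_marginal_baselined", "dro_metric_auc")`. Pooled ERM always runs
#'   (it is the reference).
#' @param model_specs List of [model_spec()]s for the stage-1 grid.
#' @param eta_grid,C_grid DRO hyperparameter grids (defaults {1, 0.1, 0.01}).
#' @param samplers Sampling rules explored for DRO (default pooled and
#'   balanced).
#' @param stop_criteria Early-stopping criteria explored in stage 1.
#' @param selection_criterion Worst-case selection rule for stage-2
#'   approaches (`"worst_group_loss"` or `"worst_group_auc"`).
#' @param train_config Base [train_config()] (epochs, batches, batch size,
#'   patience); criterion/sampler fields are overridden per grid point.
#' @param metrics Metrics for the test-set report.
#' @param B Bootstrap samples for the report.
#' @param seed Master seed.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(scenario = NULL, cohort_path = NULL,
                              schema = list(), n = 2000L,
                              approaches = c("balanced_erm",
                                             "dro_unadjusted"),
                              model_specs = list(model_spec("logistic")),
                              eta_grid = c(1, 0.1, 0.01),
                              C_grid = c(1, 0.1, 0.01),
                              samplers = c("pooled", "balanced"),
                              stop_criteria = "population_loss",
                              selection_criterion = "worst_group_loss",
                              train_config = groupdro::train_config(),
                              metrics = c("auc", "loss"),
                              B = 1000L, seed = 1L) {
  all_app <- c("balanced_erm", "stratified_erm", "dro_unadjusted",
               "dro_reciprocal_size", "dro_proportional_size",
               "dro_marginal_baselined", "dro_metric_auc")
  stopifnot(all(approaches %in% all_app),
            xor(is.null(scenario), is.null(cohort_path)) ||
              !is.null(scenario))
  structure(list(scenario = scenario, cohort_path = cohort_path,
                 schema = schema, n = as.integer(n),
                 approaches = approaches, model_specs = model_specs,
                 eta_grid = eta_grid, C_grid = C_grid, samplers = samplers,
                 stop_criteria = stop_criteria,
                 selection_criterion = selection_criterion,
                 train_config = train_config, metrics = metrics,
                 B = as.integer(B), seed = as.integer(seed)),
            class = "experiment_config")
}

approach_objective <- function(approach, eta = 1, C = 1) {
  switch(approach,
    pooled_erm = ,
    balanced_erm = ,
    stratified_erm = objective_config("erm"),
    dro_unadjusted = objective_config("dro_unadjusted", eta = eta),
    dro_reciprocal_size = objective_config("dro_reciprocal_size",
                                           eta = eta, C = C),
    dro_proportional_size = objective_config("dro_proportional_size",
                                             eta = eta, C = C),
    dro_marginal_baselined = objective_config("dro_marginal_baselined",
                                              eta = eta),
    dro_metric_auc = objective_config("dro_metric", eta = eta,
                                      metric = "auc"),
    abort(paste0("unknown approach: ", approach)))
}

# grids for one approach, with the model spec fixed (stage 2)
approach_grid <- function(approach, fixed_spec, cfg) {
  base_tc <- cfg$train_config
  if (approach == "balanced_erm") {
    tc <- base_tc; tc$sampler <- "balanced"
    return(list(grid_config(fixed_spec, objective_config("erm"), tc,
                            id = "balanced_erm")))
  }
  is_size <- approach %in% c("dro_reciprocal_size", "dro_proportional_size")
  Cs <- if (is_size) cfg$C_grid else 1
  out <- list()
  for (eta in cfg$eta_grid) for (C in Cs) for (sm in cfg$samplers) {
    tc <- base_tc
    tc$sampler <- sm
    tc$criterion <- "weighted_objective"
    id <- paste0(approach, "|eta=", eta,
                 if (is_size) paste0("|C=", C), "|", sm)
    out[[length(out) + 1]] <-
      grid_config(fixed_spec, approach_objective(approach, eta, C), tc,
                  id = id)
  }
  out
}

#' Run a full experiment
#'
#' See [experiment_config()] for the staged procedure. All artifacts are
#' written under `outdir`: the run manifest with every derived sub-seed
#' (`manifest.json`), per-approach selection tables, and per-approach
#' test-set reports (CSV and JSON), absolute and relative to pooled ERM.
#'
#' @param config An [experiment_config()].
#' @param outdir Output directory (created if needed).
#' @param verbosity 0 silent, 1 stage progress, 2 per-config progress.
#' @return Invisibly, a list with the cohort, splits, per-approach selected
#'   configs and `reports` (named list of [bootstrap_report()] tibbles).
#' @export
run_experiment <- function(config, outdir, verbosity = 1) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(lvl, ...) if (verbosity >= lvl) message(...)
  seed <- config$seed

  cohort <- if (!is.null(config$scenario)) {
    generate_cohort(config$scenario, config$n,
                    seed = derive_seed(seed, "cohort"))
  } else {
    read_cohort(config$cohort_path, config$schema)
  }
  splits <- assign_splits(cohort, seed = derive_seed(seed, "splits"))
  test <- split_part(cohort, splits, "test")
  lv <- group_levels(cohort)

  # stage 1: pooled ERM grid, selection by overall validation loss
  say(1, "stage 1: pooled ERM grid (", length(config$model_specs), " spec(s), ",
      length(config$stop_criteria), " criterion(s))")
  grid1 <- list()
  for (si in seq_along(config$model_specs)) {
    for (crit in config$stop_criteria) {
      tc <- config$train_config
      tc$criterion <- crit
      tc$sampler <- "pooled"
      grid1[[length(grid1) + 1]] <-
        grid_config(config$model_specs[[si]], objective_config("erm"), tc,
                    id = paste0("pooled_erm|spec", si, "|", crit))
    }
  }
  res1 <- run_grid(cohort, splits, grid1, seed = derive_seed(seed, "grid1"))
  sel_erm <- select_config(res1, "population_loss")
  fixed_spec <- sel_erm$config[[1]]$model_spec
  say(1, "  selected: ", sel_erm$config_id)

  selected <- list(pooled_erm = sel_erm)
  # stage 2: alternatives with model-class hyperparameters fixed
  for (app in config$approaches) {
    say(1, "stage 2: ", app)
    if (app == "stratified_erm") {
      tc <- config$train_config
      tc$criterion <- "population_loss"   # per-group loss on group data
      sgrid <- list(grid_config(fixed_spec, objective_config("erm"), tc,
                                id = "stratified_erm"))
      selected[[app]] <- stratified_erm(cohort, splits, sgrid,
                                        seed = derive_seed(seed, app))
    } else {
      g <- approach_grid(app, fixed_spec, config)
      say(2, "  grid size: ", length(g))
      res <- run_grid(cohort, splits, g, seed = derive_seed(seed, app))
      selected[[app]] <- select_config(res, config$selection_criterion)
      say(1, "  selected: ", selected[[app]]$config_id)
    }
  }

  # stage 3: test-set reports, absolute and relative to pooled ERM
  say(1, "stage 3: test-set bootstrap reports (B = ", config$B, ")")
  test_preds <- function(sel) {
    if (inherits(sel, "dro_stratified")) {
      purrr::map(seq_along(sel$selected[[1]]$fits[[1]]), function(r) {
        prediction_set(predict(sel, test, replicate = r), test$outcome,
                       test$group, replicate = r)
      })
    } else {
      purrr::map(seq_along(sel$fits[[1]]), function(r) {
        prediction_set(predict(sel$fits[[1]][[r]]$model, test),
                       test$outcome, test$group, replicate = r)
      })
    }
  }
  erm_preds <- test_preds(selected$pooled_erm)
  reports <- list()
  for (app in names(selected)) {
    preds <- if (app == "pooled_erm") erm_preds else test_preds(selected[[app]])
    reports[[app]] <- bootstrap_report(
      preds, reference = erm_preds, metrics = config$metrics,
      B = config$B, seed = derive_seed(seed, "bootstrap", app),
      group_levels_ = lv)
    write_report(reports[[app]],
                 file.path(outdir, paste0("report_", app, ".csv")),
                 config_id = app)
    write_report(reports[[app]],
                 file.path(outdir, paste0("report_", app, ".json")),
                 config_id = app)
  }

  manifest <- list(
    seed = seed,
    sub_seeds = list(cohort = derive_seed(seed, "cohort"),
                     splits = derive_seed(seed, "splits"),
                     grid1 = derive_seed(seed, "grid1")),
    approaches = names(selected),
    selected = lapply(selected, function(s) {
      if (inherits(s, "dro_stratified")) {
        lapply(s$selected, function(x) x$config_id)
      } else s$config_id
    }),
    n = nrow(cohort), groups = lv, B = config$B
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  say(1, "done: ", outdir)
  invisible(list(cohort = cohort, splits = splits, selected = selected,
                 reports = reports))
}
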