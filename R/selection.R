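#' Random train / validation / test split with cross-validation folds
#'
#' 62.5% train, 12.5% validation, 25% test, at the individual level; the
#' training portion is further partitioned into five equally sized (within
#' one) folds, each of which serves once as the development set for early
#' stopping while the other four are trained on.
#'
#' @param cohort A cohort.
#' @param seed Integer seed.
#' @param fractions Named numeric vector `c(train=, validation=, test=)`
#'   summing to 1.
#' @param n_folds Number of folds on the training portion (default 5).
#' @return A tibble `id`, `role` (`train`/`validation`/`test`), `fold`
#'   (integer for training rows, `NA` otherwise).
#' @export
assign_splits <- function(cohort, seed = 1L,
                          fractions = c(train = 0.625, validation = 0.125,
                                        test = 0.25),
                          n_folds = 5L) {
  n <- nrow(cohort)
  stopifnot(n >= 8, abs(sum(fractions) - 1) < 1e-9)
  n_train <- round(fractions[["train"]] * n)
  n_val <- round(fractions[["validation"]] * n)
  n_test <- n - n_train - n_val
  withr::with_seed(derive_seed(seed, "splits"), {
    perm <- sample.int(n)
    role <- character(n)
    role[perm[seq_len(n_train)]] <- "train"
    role[perm[n_train + seq_len(n_val)]] <- "validation"
    role[perm[n_train + n_val + seq_len(n_test)]] <- "test"
    fold <- rep(NA_integer_, n)
    tr <- perm[seq_len(n_train)]
    fold[tr] <- rep_len(seq_len(n_folds), n_train)[sample.int(n_train)]
  })
  tibble::tibble(id = cohort$id, role = role, fold = fold)
}

# helper: sub-cohorts by role / fold
split_part <- function(cohort, splits, role_, fold_ = NULL,
                       exclude_fold = NULL) {
  sel <- splits$role == role_
  if (!is.null(fold_)) sel <- sel & !is.na(splits$fold) & splits$fold == fold_
  if (!is.null(exclude_fold)) {
    sel <- sel & !is.na(splits$fold) & splits$fold != exclude_fold
  }
  cohort_slice(cohort, which(sel))
}

#' Declare one grid configuration
#'
#' @param model_spec A [model_spec()].
#' @param objective An [objective_config()].
#' @param train_config A [train_config()].
#' @param id Optional identifier; defaults to a compact description.
#' @return A `grid_config` list.
#' @export
grid_config <- function(model_spec, objective, train_config, id = NULL) {
  id <- id %||% paste(objective$variant, model_spec$family,
                      train_config$sampler, train_config$criterion,
                      sep = "|")
  structure(list(id = id, model_spec = model_spec, objective = objective,
                 train_config = train_config),
            class = "grid_config")
}

#' Run a hyperparameter grid with five-fold replicate training
#'
#' For every configuration and every fold `f`, trains a model on the
#' training folds excluding `f` with fold `f` as the development set, then
#' scores the validation set. Per-group validation metrics (AUC and loss)
#' are averaged over the five replicates.
#'
#' @param cohort A cohort.
#' @param splits An [assign_splits()] tibble.
#' @param grid List of [grid_config()]s.
#' @param seed Master seed; each (config, fold) replicate draws independent
#'   substreams for initialization and sampling.
#' @param keep_fits Keep the trained replicate models (needed for test-set
#'   scoring); default `TRUE`.
#' @return A `dro_grid` tibble with one row per config: `config_id`,
#'   list-columns `config`, `fits`, `val_predictions` (5 prediction sets),
#'   and `metrics` (nested tibble `population`, `metric`, `value`:
#'   replicate-averaged validation AUC / loss for the overall population,
#'   each group, and the worst case).
#' @export
run_grid <- function(cohort, splits, grid, seed = 1L, keep_fits = TRUE) {
  stopifnot(length(grid) >= 1)
  folds <- sort(unique(splits$fold[!is.na(splits$fold)]))
  val <- split_part(cohort, splits, "validation")
  lv <- group_levels(cohort)
  rows <- purrr::map_dfr(seq_along(grid), function(ci) {
    cfg <- grid[[ci]]
    reps <- purrr::map(folds, function(f) {
      ms <- cfg$model_spec
      ms$init_seed <- derive_seed(seed, "init", cfg$id, f)
      tc <- cfg$train_config
      tc$seed <- derive_seed(seed, "train", cfg$id, f)
      tr <- split_part(cohort, splits, "train", exclude_fold = f)
      dev <- split_part(cohort, splits, "train", fold_ = f)
      fit <- train_model(build_model(ms, length(feature_cols(cohort))),
                         cfg$objective, tr, dev, tc)
      ps <- prediction_set(predict(fit$model, val), val$outcome, val$group,
                           replicate = f)
      list(fit = fit, ps = ps)
    })
    preds <- purrr::map(reps, "ps")
    metrics <- aggregate_val_metrics(preds, lv)
    tibble::tibble(
      config_id = cfg$id,
      config = list(cfg),
      fits = if (keep_fits) list(purrr::map(reps, "fit")) else list(NULL),
      val_predictions = list(preds),
      metrics = list(metrics)
    )
  })
  structure(rows, class = c("dro_grid", class(rows)))
}

# replicate-averaged per-population validation metrics (auc + loss)
aggregate_val_metrics <- function(preds, lv) {
  K <- length(lv)
  per_rep <- purrr::map(preds, function(ps) {
    codes <- group_codes(ps$group, lv)
    population_metrics(ps$score, ps$outcome, codes, K, lv,
                       metrics = c("auc", "loss"))
  })
  purrr::map_dfr(c("auc", "loss"), function(metric) {
    mat <- do.call(rbind, purrr::map(per_rep, metric))
    tibble::tibble(population = colnames(mat), metric = metric,
                   value = unname(colMeans(mat)))
  })
}

#' Select a configuration from grid results
#'
#' Selection mirrors the early-stopping criteria, applied to replicate-
#' averaged validation metrics: `"population_loss"` minimizes overall loss
#' (the standard pooled-ERM rule); `"worst_group_loss"` minimizes the
#' maximum per-group loss; `"worst_group_auc"` maximizes the minimum
#' per-group AUC. Exact ties go to the earliest config in grid order.
#'
#' @param grid_results A [run_grid()] result.
#' @param criterion Selection criterion.
#' @return The winning row of `grid_results` (a one-row `dro_grid`), with
#'   attribute `selection_value`.
#' @export
select_config <- function(grid_results,
                          criterion = c("population_loss",
                                        "worst_group_loss",
                                        "worst_group_auc")) {
  criterion <- match.arg(criterion)
  stopifnot(nrow(grid_results) >= 1)
  score <- vapply(grid_results$metrics, function(mt) {
    switch(criterion,
      population_loss = mt$value[mt$population == "overall" &
                                   mt$metric == "loss"],
      worst_group_loss = mt$value[mt$population == "worst_case" &
                                    mt$metric == "loss"],
      worst_group_auc = -mt$value[mt$population == "worst_case" &
                                    mt$metric == "auc"])
  }, numeric(1))
  if (all(is.na(score))) abort("no config with a defined selection value")
  best <- which.min(score)    # ties: first in grid order
  out <- grid_results[best, ]
  attr(out, "selection_value") <- score[best]
  out
}

#' Stratified ERM: a separate pipeline per subpopulation
#'
#' Runs the full grid + selection independently on each group's data
#' (selection by that group's average validation loss), producing one chosen
#' configuration and model set per group. Prediction routes each individual
#' to their group's models.
#'
#' @param cohort A cohort.
#' @param splits An [assign_splits()] tibble.
#' @param grid List of [grid_config()]s (objectives should be ERM).
#' @param seed Master seed.
#' @return A `dro_stratified` list: per-group one-row grids (`selected`),
#'   keyed by group name.
#' @export
stratified_erm <- function(cohort, splits, grid, seed = 1L) {
  lv <- group_levels(cohort)
  selected <- lapply(lv, function(g) {
    sel <- cohort$group == g
    sub <- cohort_slice(cohort, which(sel))
    attr(sub, "group_levels") <- g       # single-group vocabulary
    ssub <- splits[sel, , drop = FALSE]
    if (!all(c("train", "validation") %in% ssub$role)) {
      abort(paste0("empty partition for group ", g),
            class = "groupdro_config_error")
    }
    res <- run_grid(sub, ssub, grid, seed = derive_seed(seed, "strat", g))
    select_config(res, "population_loss")
  })
  names(selected) <- lv
  structure(list(selected = selected, group_levels = lv),
            class = "dro_stratified")
}

#' Predict with a stratified model set
#'
#' @param object A [stratified_erm()] result.
#' @param newdata A cohort containing only groups the object was trained on.
#' @param replicate Which of the fold replicates to use (default 1).
#' @param ... Unused.
#' @return Numeric score vector, each individual scored by their group's
#'   model.
#' @export
predict.dro_stratified <- function(object, newdata, replicate = 1L, ...) {
  out <- rep(NA_real_, nrow(newdata))
  X <- feature_matrix(newdata)
  for (g in object$group_levels) {
    sel <- newdata$group == g
    if (!any(sel)) next
    fit <- object$selected[[g]]$fits[[1]][[replicate]]
    out[sel] <- predict(fit$model, X[sel, , drop = FALSE])
  }
  if (anyNA(out)) abort("individuals from groups without a stratified model")
  out
}
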