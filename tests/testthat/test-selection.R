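test_that("split fractions, disjointness, folds and determinism", {
  co <- generate_cohort(demo_scenario(3), 1000)
  sp <- assign_splits(co, seed = 4)
  expect_equal(sum(sp$role == "train"), 625)
  expect_equal(sum(sp$role == "validation"), 125)
  expect_equal(sum(sp$role == "test"), 250)
  expect_true(all(table(sp$fold[!is.na(sp$fold)]) == 125))
  expect_true(all(sp$role %in% c("train", "validation", "test")))
  expect_true(all(is.na(sp$fold[sp$role != "train"])))
  expect_identical(assign_splits(co, seed = 4), sp)
  expect_false(identical(assign_splits(co, seed = 5), sp))
})

# build a mock grid row with prescribed per-population metrics
mock_grid <- function(metric_tables) {
  rows <- purrr::map_dfr(seq_along(metric_tables), function(i) {
    tibble::tibble(config_id = paste0("cfg", i), config = list(NULL),
                   fits = list(NULL), val_predictions = list(NULL),
                   metrics = list(metric_tables[[i]]))
  })
  structure(rows, class = c("dro_grid", class(rows)))
}

mock_metrics <- function(overall_loss, g_losses, g_aucs) {
  pops <- c("overall", paste0("g", seq_along(g_losses)), "worst_case")
  tibble::tibble(
    population = rep(pops, 2),
    metric = rep(c("auc", "loss"), each = length(pops)),
    value = c(mean(g_aucs), g_aucs, min(g_aucs),
              overall_loss, g_losses, max(g_losses)))
}

test_that("selection criteria pick the best worst case with deterministic ties", {
  m1 <- mock_metrics(0.40, c(0.35, 0.55), c(0.80, 0.70))
  m2 <- mock_metrics(0.45, c(0.44, 0.46), c(0.82, 0.80))
  g <- mock_grid(list(m1, m2))
  expect_equal(select_config(g, "population_loss")$config_id, "cfg1")
  expect_equal(select_config(g, "worst_group_loss")$config_id, "cfg2")
  expect_equal(select_config(g, "worst_group_auc")$config_id, "cfg2")
  # single config chosen under any criterion; exact tie -> first in order
  expect_equal(select_config(mock_grid(list(m1)), "worst_group_auc")$config_id,
               "cfg1")
  expect_equal(select_config(mock_grid(list(m1, m1)),
                             "worst_group_loss")$config_id, "cfg1")
})

test_that("selection equals an exhaustive scan on randomized mock grids", {
  withr::with_seed(77, {
    for (rep in 1:200) {
      nc <- sample(2:6, 1)
      tabs <- lapply(seq_len(nc), function(i) {
        mock_metrics(runif(1, 0.2, 0.8), runif(3, 0.2, 0.9),
                     runif(3, 0.5, 0.99))
      })
      g <- mock_grid(tabs)
      wl <- vapply(tabs, function(t) {
        t$value[t$population == "worst_case" & t$metric == "loss"]
      }, numeric(1))
      wa <- vapply(tabs, function(t) {
        t$value[t$population == "worst_case" & t$metric == "auc"]
      }, numeric(1))
      ol <- vapply(tabs, function(t) {
        t$value[t$population == "overall" & t$metric == "loss"]
      }, numeric(1))
      expect_equal(select_config(g, "worst_group_loss")$config_id,
                   paste0("cfg", which.min(wl)))
      expect_equal(select_config(g, "worst_group_auc")$config_id,
                   paste0("cfg", which.max(wa)))
      expect_equal(select_config(g, "population_loss")$config_id,
                   paste0("cfg", which.min(ol)))
    }
  })
})

test_that("run_grid trains five replicates and averages their metrics", {
  co <- generate_cohort(demo_scenario(5), 900)
  sp <- assign_splits(co, seed = 6)
  tc <- train_config(max_epochs = 2, batches_per_epoch = 4, batch_size = 64,
                     patience = 2)
  grid <- list(grid_config(model_spec("logistic", learning_rate = 0.05),
                           objective_config("erm"), tc, id = "only"))
  res <- run_grid(co, sp, grid, seed = 8)
  expect_equal(nrow(res), 1)
  expect_length(res$fits[[1]], 5)
  expect_length(res$val_predictions[[1]], 5)

  # aggregated group AUC equals the mean of the five replicate group AUCs
  lv <- group_levels(co)
  per_rep <- vapply(res$val_predictions[[1]], function(ps) {
    sel <- ps$group == lv[1]
    auc(ps$score[sel], ps$outcome[sel])
  }, numeric(1))
  mt <- res$metrics[[1]]
  expect_equal(mt$value[mt$population == lv[1] & mt$metric == "auc"],
               mean(per_rep), tolerance = 1e-12)

  # end-to-end reproducibility of the grid
  res2 <- run_grid(co, sp, grid, seed = 8)
  expect_equal(res$metrics[[1]], res2$metrics[[1]], tolerance = 1e-15)
})

test_that("stratified training selects and routes per group", {
  sp <- conflict_scenario(0.35, m = 2, seed = 31)
  co <- generate_cohort(sp, 3000)
  splits <- assign_splits(co, seed = 32)
  tc <- train_config(max_epochs = 6, batches_per_epoch = 6,
                     batch_size = 128, patience = 6)
  grid <- list(grid_config(model_spec("logistic", learning_rate = 0.05),
                           objective_config("erm"), tc, id = "erm"))
  strat <- stratified_erm(co, splits, grid, seed = 33)
  expect_named(strat$selected, c("majority", "minority"))

  test <- groupdro:::split_part(co, splits, "test")
  s_strat <- predict(strat, test)
  gl_s <- group_losses(s_strat, test$outcome, test$group, group_levels(co))

  # a capacity-limited pooled model cannot match per-group fits on both groups
  pooled <- run_grid(co, splits, grid, seed = 34)
  s_pool <- predict(pooled$fits[[1]][[1]]$model, test)
  gl_p <- group_losses(s_pool, test$outcome, test$group, group_levels(co))
  expect_true(all(gl_s$loss < gl_p$loss))
})
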