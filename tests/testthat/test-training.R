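test_that("criterion values: identities and arithmetic", {
  s <- c(0.8, 0.3, 0.6, 0.2, 0.9, 0.4)
  y <- c(1, 0, 1, 0, 1, 0)
  g1 <- rep("only", 6)
  expect_equal(criterion_value("population_loss", s, y, g1),
               criterion_value("worst_group_loss", s, y, g1))

  g <- rep(c("a", "b"), each = 3)
  aucs <- c(auc(s[1:3], y[1:3]), auc(s[4:6], y[4:6]))
  expect_equal(criterion_value("worst_group_auc", s, y, g), -min(aucs))

  gl <- group_losses(s, y, g)
  expect_equal(criterion_value("weighted_objective", s, y, g,
                               lambda = c(0.5, 0.5)),
               0.5 * gl$loss[1] + 0.5 * gl$loss[2])
})

test_that("training loop: epochs, patience contract, best-model restore", {
  co <- generate_cohort(demo_scenario(1), 1200)
  parts <- simple_split(co, 0.25, seed = 2)
  spec <- model_spec("logistic", learning_rate = 0.05, init_seed = 4)
  tc1 <- train_config(max_epochs = 1, batches_per_epoch = 5,
                      batch_size = 128, patience = 1, seed = 6)
  fit1 <- train_model(build_model(spec, 3), objective_config("erm"),
                      parts$train, parts$dev, tc1)
  expect_equal(fit1$stopped_epoch, 1)
  expect_equal(fit1$best_epoch, 1)
  expect_equal(nrow(fit1$history), 1)

  tc <- train_config(max_epochs = 40, batches_per_epoch = 5,
                     batch_size = 128, patience = 4, seed = 6)
  fit <- train_model(build_model(spec, 3), objective_config("erm"),
                     parts$train, parts$dev, tc)
  # best criterion value is the minimum of the history
  expect_equal(fit$best_value, min(fit$history$criterion))
  # stops patience epochs after the last improvement (unless budget hit)
  if (fit$stopped_epoch < tc$max_epochs) {
    expect_equal(fit$stopped_epoch, fit$best_epoch + tc$patience)
  }
  # restored snapshot reproduces the best dev criterion
  sdev <- predict(fit$model, parts$dev)
  expect_equal(mean_loss(sdev, parts$dev$outcome), fit$best_value,
               tolerance = 1e-12)
  # tidy/glance accessors
  expect_true(all(c("epoch", "series", "value") %in% names(tidy(fit))))
  expect_equal(glance(fit)$best_epoch, fit$best_epoch)
})

test_that("single-group DRO reproduces ERM exactly under a shared seed", {
  sp <- scenario_spec(c(1), c(0.2), list(c(1, -1)), seed = 8)
  co <- generate_cohort(sp, 800)
  parts <- simple_split(co, 0.25, seed = 3)
  spec <- model_spec("logistic", learning_rate = 0.02, init_seed = 9)
  tc <- train_config(max_epochs = 5, batches_per_epoch = 8,
                     batch_size = 64, patience = 5, seed = 10)
  fit_erm <- train_model(build_model(spec, 2), objective_config("erm"),
                         parts$train, parts$dev, tc)
  fit_dro <- train_model(build_model(spec, 2),
                         objective_config("dro_unadjusted", eta = 1),
                         parts$train, parts$dev, tc)
  expect_identical(groupdro:::model_params(fit_erm$model),
                   groupdro:::model_params(fit_dro$model))
  expect_identical(fit_erm$history$criterion, fit_dro$history$criterion)
})

test_that("lambda trajectory stays on the simplex and shifts toward the harder group", {
  sp <- conflict_scenario(0.3, m = 2, seed = 12)
  co <- generate_cohort(sp, 4000)
  parts <- simple_split(co, 0.2, seed = 5)
  tc <- train_config(max_epochs = 8, batches_per_epoch = 10,
                     batch_size = 256, patience = 8,
                     criterion = "weighted_objective",
                     sampler = "balanced", seed = 13)
  fit <- train_model(build_model(model_spec("logistic",
                                            learning_rate = 0.02,
                                            init_seed = 3), 2),
                     objective_config("dro_unadjusted", eta = 0.5),
                     parts$train, parts$dev, tc)
  lam <- as.matrix(fit$history[, c("lambda_majority", "lambda_minority")])
  expect_true(all(lam >= 0))
  expect_equal(rowSums(lam), rep(1, nrow(lam)), tolerance = 1e-9)
  # the underserved minority accumulates weight
  expect_gt(fit$lambda[["minority"]], 0.5)
})

test_that("worst_group_auc setup rejects single-class dev groups", {
  df <- data.frame(id = 1:40, group = rep(c("a", "b"), each = 20),
                   outcome = c(rbinom(20, 1, 0.5), rep(0, 20)),
                   x = rnorm(40))
  co <- as_cohort(df)
  parts <- list(train = groupdro:::cohort_slice(co, 1:30),
                dev = groupdro:::cohort_slice(co, 31:40))
  tc <- train_config(max_epochs = 2, batches_per_epoch = 2, batch_size = 10,
                     patience = 2, criterion = "worst_group_auc", seed = 1)
  expect_error(train_model(build_model(model_spec("logistic"), 1),
                           objective_config("erm"), parts$train, parts$dev,
                           tc),
               class = "groupdro_config_error")
})

test_that("feedforward networks train with dropout and improve on init", {
  co <- generate_cohort(demo_scenario(7), 1500)
  parts <- simple_split(co, 0.2, seed = 7)
  spec <- model_spec("feedforward", hidden_layers = 1, hidden_size = 16,
                     dropout = 0.25, learning_rate = 0.01, init_seed = 2)
  model0 <- build_model(spec, 3)
  loss0 <- mean_loss(predict(model0, parts$dev), parts$dev$outcome)
  tc <- train_config(max_epochs = 10, batches_per_epoch = 10,
                     batch_size = 128, patience = 10, seed = 3)
  fit <- train_model(model0, objective_config("dro_unadjusted", eta = 0.1),
                     parts$train, parts$dev, tc)
  expect_lt(fit$best_value, loss0)
})
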