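test_that("per-group losses match direct computation", {
  # all scores 0.5 -> every present group's loss is ln 2
  gl <- group_losses(rep(0.5, 4), c(1, 0, 1, 0), c("a", "a", "b", "b"))
  expect_equal(gl$loss, rep(log(2), 2), tolerance = 1e-12)

  # 6-point two-group example vs element-wise arithmetic
  s <- c(0.9, 0.2, 0.6, 0.4, 0.7, 0.05)
  y <- c(1, 0, 1, 0, 0, 0)
  g <- c("a", "a", "a", "b", "b", "b")
  li <- -(y * log(s) + (1 - y) * log(1 - s))
  gl2 <- group_losses(s, y, g)
  expect_equal(gl2$loss, c(mean(li[1:3]), mean(li[4:6])), tolerance = 1e-12)

  # K = 1 equals pooled mean; absent groups flagged
  expect_equal(group_losses(s, y, rep("z", 6))$loss, mean(li))
  gl3 <- group_losses(s[1:3], y[1:3], g[1:3], levels = c("a", "b"))
  expect_false(gl3$present[2])
  expect_true(is.na(gl3$loss[2]))
})

test_that("exponentiated-gradient update matches the softmax closed form", {
  lam <- update_weights(c(0.5, 0.5), badness = c(1, 0), eta = 1)
  expect_equal(lam, c(exp(1), 1) / (1 + exp(1)), tolerance = 1e-12)
  expect_equal(lam, c(0.7311, 0.2689), tolerance = 1e-4)

  # equal badness leaves lambda unchanged; shift invariance
  expect_equal(update_weights(c(0.3, 0.7), c(2, 2), 1), c(0.3, 0.7))
  a <- update_weights(c(0.2, 0.8), c(0.4, -1.2), 0.5)
  b <- update_weights(c(0.2, 0.8), c(0.4, -1.2) + 10, 0.5)
  expect_equal(a, b, tolerance = 1e-12)

  # repeated updates with fixed badness (1, 0): lambda_1 -> 1 monotonically,
  # matching the closed-form iterate lam1 * e^(t*eta) / (lam1 e^(t*eta) + lam2)
  lam <- c(0.5, 0.5)
  prev <- lam[1]
  for (t in 1:50) {
    lam <- update_weights(lam, c(1, 0), 0.1)
    expect_gt(lam[1], prev)
    expect_equal(lam[1], 0.5 * exp(0.1 * t) / (0.5 * exp(0.1 * t) + 0.5),
                 tolerance = 1e-12)
    prev <- lam[1]
  }

  # absent group keeps its unnormalized mass
  lam2 <- update_weights(c(0.25, 0.25, 0.5), c(1, NA, 0), 1,
                         present = c(TRUE, FALSE, TRUE))
  byhand <- c(0.25 * exp(1), 0.25, 0.5)
  expect_equal(lam2, byhand / sum(byhand), tolerance = 1e-12)

  expect_error(update_weights(c(0.5, 0.5), c(Inf, 0), 1), "non-finite")
})

test_that("additive adjustment formulas", {
  mk_stats <- function(frac, q = rep(0.5, length(frac)), N = 1000) {
    tibble::tibble(group = paste0("g", seq_along(frac)),
                   n = round(frac * N), fraction = frac, incidence = q)
  }
  # reciprocal C / p_k
  st <- mk_stats(c(0.1, 0.9))
  expect_equal(compute_adjustment(objective_config("dro_reciprocal_size",
                                                   C = 1), st),
               c(10, 1 / 0.9), tolerance = 1e-12)
  # proportional C * sqrt(n_k / N)
  st2 <- mk_stats(c(0.25, 0.75))
  expect_equal(compute_adjustment(objective_config("dro_proportional_size",
                                                   C = 1), st2),
               c(0.5, sqrt(0.75)), tolerance = 1e-12)
  # marginal baseline: negative entropy; q = 0.5 -> -ln 2
  st3 <- mk_stats(c(0.5, 0.5), q = c(0.5, 0.0162))
  adj <- compute_adjustment(
    objective_config("dro_marginal_baselined",
                     entropy_source = "precomputed"), st3)
  expect_equal(adj[1], -log(2), tolerance = 1e-12)
  expect_equal(adj[2], 0.0162 * log(0.0162) + (1 - 0.0162) * log(1 - 0.0162),
               tolerance = 1e-12)

  # minibatch source estimates incidence from the batch, clipping degenerate 0/1
  cfg <- objective_config("dro_marginal_baselined",
                          entropy_source = "minibatch")
  adj2 <- compute_adjustment(cfg, st3,
                             minibatch_outcomes = c(1, 0, 1, 1, 1, 1),
                             minibatch_groups = c("g1", "g1", "g2", "g2",
                                                  "g2", "g2"))
  expect_equal(adj2[1], -log(2), tolerance = 1e-12)
  q2 <- 1 - 1e-7
  expect_equal(adj2[2], q2 * log(q2) + (1 - q2) * log(1 - q2),
               tolerance = 1e-12)

  # unadjusted / erm / metric variants give zero
  expect_equal(compute_adjustment(objective_config("dro_unadjusted"), st),
               c(0, 0))
  st0 <- mk_stats(c(0, 1))
  expect_error(compute_adjustment(objective_config("dro_reciprocal_size"),
                                  st0),
               class = "groupdro_config_error")
})

test_that("strict pairwise AUC complement matches brute force, including ties", {
  expect_equal(g_auc(c(0.9, 0.1), c(1, 0)), 0)
  expect_equal(g_auc(c(0.1, 0.9), c(1, 0)), 1)
  # 5 points with one discordant pair and one tie
  s <- c(0.8, 0.5, 0.3, 0.5, 0.6)
  y <- c(1, 1, 0, 0, 0)
  expect_equal(g_auc(s, y), brute_g_auc(s, y), tolerance = 1e-12)
  expect_true(is.na(g_auc(c(0.1, 0.9), c(1, 1))))

  withr::with_seed(19, {
    for (i in 1:200) {
      n <- sample(4:50, 1)
      # coarse scores force ties
      s <- sample(seq(0, 1, 0.1), n, replace = TRUE)
      y <- rbinom(n, 1, 0.4)
      expect_identical(g_auc(s, y), brute_g_auc(s, y))
    }
  })
})

test_that("weighted loss arithmetic", {
  expect_equal(weighted_loss(c(0.5, 0.5), c(1, 2)), 1.5)
  expect_equal(weighted_loss(c(0, 1), c(1, 2)), 2)
  expect_equal(weighted_loss(c(0.3, 0.7), c(1, 2)), 1.7)
  # absent group contributes nothing (no renormalization)
  expect_equal(weighted_loss(c(0.3, 0.7), c(1, NA)), 0.3)
  gl <- group_losses(c(0.5, 0.5), c(1, 0), c("a", "b"))
  expect_equal(weighted_loss(c(0.5, 0.5), gl), log(2))
})
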