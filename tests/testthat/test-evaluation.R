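test_that("tie-aware AUC matches brute force and an independent implementation", {
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc(rep(0.4, 6), c(1, 0, 1, 0, 0, 1)), 0.5)
  s8 <- c(0.1, 0.5, 0.5, 0.7, 0.3, 0.9, 0.2, 0.5)
  y8 <- c(0, 1, 0, 1, 0, 1, 1, 0)
  expect_equal(auc(s8, y8), brute_auc(s8, y8), tolerance = 1e-12)
  expect_true(is.na(auc(c(0.2, 0.3), c(1, 1))))

  withr::with_seed(91, {
    for (i in 1:50) {
      n <- sample(5:60, 1)
      s <- sample(seq(0, 1, 0.05), n, replace = TRUE)
      y <- rbinom(n, 1, 0.5)
      if (length(unique(y)) < 2) next
      expect_equal(auc(s, y), brute_auc(s, y), tolerance = 1e-12)
    }
  })
  if (requireNamespace("pROC", quietly = TRUE)) {
    withr::with_seed(92, {
      s <- runif(200); y <- rbinom(200, 1, 0.3)
      expect_equal(auc(s, y),
                   as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                  direction = "<"))),
                   tolerance = 1e-12)
    })
  }

  # invariance under strictly increasing transforms (ACE is not invariant)
  withr::with_seed(93, {
    s <- runif(100); y <- rbinom(100, 1, plogis(3 * s - 1.5))
    expect_equal(auc(s, y), auc(plogis(5 * s - 2), y), tolerance = 1e-12)
    expect_gt(abs(ace(s, y) - ace(plogis(5 * s - 2), y)), 1e-4)
  })
})

test_that("absolute calibration error: degenerate and well-specified cases", {
  withr::with_seed(41, {
    y <- rbinom(500, 1, 0.2)
    expect_lt(ace(rep(mean(y), 500), y), 1e-8)

    # perfectly calibrated low-incidence scores: ACE -> 0
    u <- runif(2e4)
    s <- plogis(-3.5 + log(u))
    yy <- rbinom(2e4, 1, s)
    expect_lt(ace(s, yy), 0.005)

    # a constant shift is detected as miscalibration
    expect_gt(ace(clip_prob(s + 0.2), yy), 0.1)

    # logit transform variant runs and differs from the log transform once
    # scores span the full unit interval
    s3 <- runif(800, 0.05, 0.95)
    y3 <- rbinom(800, 1, plogis(2 * qlogis(s3)))
    expect_false(isTRUE(all.equal(ace(s3, y3),
                                  ace(s3, y3, transform = "logit"))))
  })
  expect_true(is.na(ace(runif(20), rep(1, 20))))
})

test_that("worst case is max for loss/ace and min for auc, NA-flagged", {
  expect_equal(worst_case(c(0.1, 0.4), "loss"), 0.4)
  expect_equal(worst_case(c(0.9, 0.7), "auc"), 0.7)
  expect_equal(worst_case(0.3, "ace"), 0.3)
  expect_true(is.na(worst_case(c(0.9, NA), "auc")))
})

test_that("stratified bootstrap preserves stratum counts and orders quantiles", {
  withr::with_seed(55, {
    n <- 300
    g <- sample(c("a", "b"), n, TRUE, prob = c(0.7, 0.3))
    y <- rbinom(n, 1, ifelse(g == "a", 0.1, 0.3))
    s <- clip_prob(runif(n))
    ps <- prediction_set(s, y, g)
    rep1 <- bootstrap_report(ps, B = 40, seed = 9, metrics = c("auc", "loss"))
    expect_s3_class(rep1, "dro_eval_report")
    expect_true(all(rep1$ci_low <= rep1$ci_high))
    expect_setequal(unique(rep1$population), c("overall", "a", "b",
                                               "worst_case"))
    # loss strata: resampled losses keep group x outcome counts, so the
    # overall loss of a constant-score predictor never varies
    cs <- prediction_set(rep(0.25, n), y, g)
    rep2 <- bootstrap_report(cs, B = 25, seed = 2, metrics = "loss")
    expect_equal(rep2$ci_low, rep2$estimate, tolerance = 1e-12)
    expect_equal(rep2$ci_high, rep2$estimate, tolerance = 1e-12)
    # difference vs self: identically zero with degenerate interval
    rep3 <- bootstrap_report(ps, reference = ps, B = 25, seed = 3,
                             metrics = "auc")
    expect_true(all(rep3$delta == 0))
    expect_true(all(rep3$delta_low == 0 & rep3$delta_high == 0))
  })
})

test_that("bootstrap pools over replicates and is seed-reproducible", {
  withr::with_seed(66, {
    n <- 200
    g <- rep(c("a", "b"), each = n / 2)
    y <- rbinom(n, 1, 0.3)
    reps <- lapply(1:5, function(r) {
      prediction_set(clip_prob(runif(n)), y, g, replicate = r)
    })
    r1 <- bootstrap_report(reps, B = 30, seed = 4, metrics = "auc")
    r2 <- bootstrap_report(reps, B = 30, seed = 4, metrics = "auc")
    expect_identical(as.data.frame(r1), as.data.frame(r2))
    # point estimate is the replicate-averaged full-sample metric
    want <- mean(vapply(reps, function(p) auc(p$score, p$outcome),
                        numeric(1)))
    expect_equal(r1$estimate[r1$population == "overall"], want,
                 tolerance = 1e-12)
    # report serialization
    p_csv <- withr::local_tempfile(fileext = ".csv")
    p_json <- withr::local_tempfile(fileext = ".json")
    write_report(r1, p_csv); write_report(r1, p_json, config_id = "x")
    expect_equal(nrow(readr::read_csv(p_csv, show_col_types = FALSE)),
                 nrow(r1))
    expect_equal(jsonlite::read_json(p_json)$B, 30)
  })
})
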