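#' Area under the ROC curve
#'
#' Mann-Whitney form: the probability that a randomly chosen positive case
#' is scored above a randomly chosen negative one, ties counted 1/2
#' (conventional rank statistic; the training-side [g_auc()] deliberately
#' uses strict comparisons instead).
#'
#' @param scores Numeric score vector.
#' @param outcomes Binary 0/1 vector.
#' @return AUC in `[0, 1]`; `NA` when only one class is present.
#' @export
auc <- function(scores, outcomes) {
  stopifnot(length(scores) == length(outcomes))
  n1 <- as.numeric(sum(outcomes == 1))
  n0 <- as.numeric(sum(outcomes == 0))
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[outcomes == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Mean cross-entropy loss
#'
#' @inheritParams auc
#' @param eps Score clipping constant.
#' @return Scalar mean of `-(y log s + (1 - y) log(1 - s))`.
#' @export
mean_loss <- function(scores, outcomes, eps = 1e-7) {
  mean(bce(outcomes, clip_prob(scores, eps)))
}

# intercept+slope logistic recalibration fit; returns fitted probabilities.
# glm.fit handles the degenerate constant-covariate case via rank deficiency.
recalibrate <- function(x, y) {
  fit <- suppressWarnings(
    glm.fit(cbind(1, x), y, family = binomial(),
            control = list(maxit = 100))
  )
  if (!fit$converged) {
    abort("ACE recalibration fit failed to converge",
          class = "groupdro_fit_error")
  }
  fit$fitted.values
}

#' Absolute calibration error
#'
#' Fits a one-covariate logistic recalibration model predicting the outcome
#' from the transformed score on the same data, and reports the mean
#' absolute difference between the model's scores and the fitted calibration
#' curve. The default transform is the natural log of the predicted
#' probability; `"logit"` is offered for sensitivity, since the
#' recalibration literature commonly uses the logit.
#'
#' @inheritParams mean_loss
#' @param transform `"log"` (default) or `"logit"`.
#' @return ACE >= 0; `NA` when only one outcome class is present.
#' @export
ace <- function(scores, outcomes, transform = c("log", "logit"),
                eps = 1e-7) {
  transform <- match.arg(transform)
  stopifnot(length(scores) == length(outcomes), length(scores) >= 10)
  if (length(unique(outcomes)) < 2) return(NA_real_)
  s <- clip_prob(scores, eps)
  x <- if (transform == "log") log(s) else qlogis(s)
  mean(abs(s - recalibrate(x, outcomes)))
}

#' Worst-case value of a per-group metric
#'
#' Maximum over groups for loss and calibration error, minimum for AUC.
#'
#' @param values Numeric vector of per-group metric values.
#' @param metric `"auc"`, `"loss"` or `"ace"`.
#' @return Scalar; `NA` (flagged worst case) if any group value is missing.
#' @export
worst_case <- function(values, metric = c("auc", "loss", "ace")) {
  metric <- match.arg(metric)
  if (length(values) == 0 || anyNA(values)) return(NA_real_)
  if (metric == "auc") min(values) else max(values)
}

#' Bundle scores for evaluation
#'
#' @param scores Numeric scores, clipped to `[eps, 1 - eps]`.
#' @param outcomes Binary 0/1 vector.
#' @param groups Group labels.
#' @param replicate Integer tag identifying which cross-validation model
#'   replicate produced the scores.
#' @param eps Clipping constant.
#' @return A `prediction_set` tibble with columns `score`, `outcome`,
#'   `group`, `replicate`.
#' @export
prediction_set <- function(scores, outcomes, groups, replicate = 1L,
                           eps = 1e-7) {
  stopifnot(length(scores) == length(outcomes),
            length(scores) == length(groups),
            all(outcomes %in% c(0, 1)))
  tibble::tibble(score = clip_prob(scores, eps),
                 outcome = as.integer(outcomes),
                 group = as.character(groups),
                 replicate = as.integer(replicate))
}

# metric value for one population of one replicate on given row indices
one_metric <- function(metric, scores, outcomes) {
  switch(metric,
         auc = auc(scores, outcomes),
         loss = mean_loss(scores, outcomes),
         ace = if (length(scores) >= 10) {
           tryCatch(ace(scores, outcomes), groupdro_fit_error = function(e) NA_real_)
         } else NA_real_)
}

# per-population (overall, each group, worst_case) metric values for one
# replicate's scores at the given indices; returns named numeric vector over
# populations for each metric in a list
population_metrics <- function(scores, outcomes, groups_codes, K, lv,
                               metrics) {
  out <- list()
  for (metric in metrics) {
    per_group <- vapply(seq_len(K), function(k) {
      sel <- groups_codes == k
      if (!any(sel)) return(NA_real_)
      one_metric(metric, scores[sel], outcomes[sel])
    }, numeric(1))
    vals <- c(one_metric(metric, scores, outcomes), per_group,
              worst_case(per_group, metric))
    names(vals) <- c("overall", lv, "worst_case")
    out[[metric]] <- vals
  }
  out
}

#' Disaggregated test-set report with stratified bootstrap intervals
#'
#' For each metric and population (overall, each subpopulation, worst case),
#' computes the point estimate (metric on the full test set, averaged over
#' model replicates) and a percentile confidence interval: `B` bootstrap
#' samples are drawn by resampling within each outcome-by-group stratum
#' (preserving stratum counts exactly); each metric is computed for every
#' replicate on every sample; the interval is the 2.5 / 97.5 percent
#' quantiles of the `B * n_replicates` pooled values. The worst-case interval
#' takes the worst case within each (sample, replicate) before pooling.
#' When a reference set is supplied, paired differences (candidate minus
#' reference) are computed on the same bootstrap indices, pairing replicates
#' in order.
#'
#' @param pred_sets A [prediction_set()] tibble or a list of them (the model
#'   replicates); all must share outcomes and groups row-for-row.
#' @param reference Optional prediction set(s) for the comparison model on
#'   the same test individuals.
#' @param metrics Subset of `c("auc", "loss", "ace")`.
#' @param B Number of bootstrap samples (default 1000).
#' @param seed Integer seed for the resampling stream.
#' @param group_levels_ Optional group vocabulary; default sorted unique.
#' @param alpha Two-sided interval level (default 0.05 for 95% CIs).
#' @return A `dro_eval_report` tibble: `population`, `metric`, `estimate`,
#'   `ci_low`, `ci_high` and, with a reference, `delta`, `delta_low`,
#'   `delta_high`. Attributes record `B`, `seed` and `alpha`.
#' @export
bootstrap_report <- function(pred_sets, reference = NULL,
                             metrics = c("auc", "loss", "ace"),
                             B = 1000L, seed = 1L, group_levels_ = NULL,
                             alpha = 0.05) {
  metrics <- match.arg(metrics, c("auc", "loss", "ace"), several.ok = TRUE)
  if (is.data.frame(pred_sets)) pred_sets <- list(pred_sets)
  if (!is.null(reference) && is.data.frame(reference)) {
    reference <- list(reference)
  }
  base <- pred_sets[[1]]
  for (ps in c(pred_sets, reference)) {
    stopifnot(identical(ps$outcome, base$outcome),
              identical(ps$group, base$group))
  }
  if (!is.null(reference) && length(reference) != length(pred_sets)) {
    abort("reference must have the same number of replicates")
  }
  lv <- group_levels_ %||% sort(unique(base$group))
  K <- length(lv)
  codes <- group_codes(base$group, lv)
  n <- nrow(base)
  R <- length(pred_sets)
  pops <- c("overall", lv, "worst_case")

  strata <- split(seq_len(n), interaction(base$outcome, codes, drop = TRUE))
  draw_indices <- function() {
    unlist(lapply(strata, function(ix) {
      ix[sample.int(length(ix), length(ix), replace = TRUE)]
    }), use.names = FALSE)
  }

  score_mat <- vapply(pred_sets, `[[`, numeric(n), "score")
  ref_mat <- if (!is.null(reference)) {
    vapply(reference, `[[`, numeric(n), "score")
  }

  # point estimates on the full test set, averaged over replicates
  est <- list(); ref_est <- list()
  for (r in seq_len(R)) {
    pm <- population_metrics(score_mat[, r], base$outcome, codes, K, lv,
                             metrics)
    for (metric in metrics) {
      est[[metric]] <- rbind(est[[metric]], pm[[metric]])
    }
    if (!is.null(reference)) {
      pmr <- population_metrics(ref_mat[, r], base$outcome, codes, K, lv,
                                metrics)
      for (metric in metrics) {
        ref_est[[metric]] <- rbind(ref_est[[metric]], pmr[[metric]])
      }
    }
  }

  # bootstrap: vals[[metric]] is (B*R) x n_pops; diffs likewise
  npop <- length(pops)
  vals <- lapply(metrics, function(m) matrix(NA_real_, B * R, npop))
  names(vals) <- metrics
  diffs <- if (!is.null(reference)) vals
  withr::with_seed(derive_seed(seed, "bootstrap"), {
    for (b in seq_len(B)) {
      idx <- draw_indices()
      y_b <- base$outcome[idx]; g_b <- codes[idx]
      for (r in seq_len(R)) {
        row <- (b - 1) * R + r
        pm <- population_metrics(score_mat[idx, r], y_b, g_b, K, lv, metrics)
        for (metric in metrics) vals[[metric]][row, ] <- pm[[metric]]
        if (!is.null(reference)) {
          pmr <- population_metrics(ref_mat[idx, r], y_b, g_b, K, lv, metrics)
          for (metric in metrics) {
            diffs[[metric]][row, ] <- pm[[metric]] - pmr[[metric]]
          }
        }
      }
    }
  })

  qs <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(c(NA_real_, NA_real_))
    quantile(x, c(alpha / 2, 1 - alpha / 2), names = FALSE, type = 7)
  }
  rows <- purrr::map_dfr(metrics, function(metric) {
    purrr::map_dfr(seq_along(pops), function(p) {
      ci <- qs(vals[[metric]][, p])
      row <- tibble::tibble(
        population = pops[p], metric = metric,
        estimate = mean(est[[metric]][, p]),
        ci_low = ci[1], ci_high = ci[2]
      )
      if (!is.null(reference)) {
        dci <- qs(diffs[[metric]][, p])
        row$delta <- row$estimate - mean(ref_est[[metric]][, p])
        row$delta_low <- dci[1]
        row$delta_high <- dci[2]
      }
      row
    })
  })
  structure(rows, B = as.integer(B), seed = as.integer(seed), alpha = alpha,
            n_replicates = R,
            class = c("dro_eval_report", class(rows)))
}

#' Write an evaluation report
#'
#' @param report A [bootstrap_report()] result.
#' @param path Output path (`.csv` or `.json`).
#' @param config_id Optional identifier recorded in the JSON provenance.
#' @return `path` invisibly.
#' @export
write_report <- function(report, path, config_id = NULL) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(config_id = config_id,
           B = attr(report, "B"), seed = attr(report, "seed"),
           alpha = attr(report, "alpha"),
           n_replicates = attr(report, "n_replicates"),
           rows = as.data.frame(report)),
      path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    readr::write_csv(tibble::as_tibble(as.data.frame(report)), path,
                     progress = FALSE)
  }
  invisible(path)
}
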