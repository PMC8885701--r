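#' Configure a training objective
#'
#' The objective family spans empirical risk minimization and five GroupDRO
#' variants. All DRO variants maintain a simplex weight vector over the K
#' subpopulations updated by exponentiated gradient ascent with rate `eta`;
#' the model parameters always descend the lambda-weighted cross-entropy.
#'
#' Variants:
#' * `erm` — pooled minibatch mean loss, no lambda.
#' * `dro_unadjusted` — badness is the per-group minibatch loss.
#' * `dro_reciprocal_size` — adds `C / p_k` (favors small groups).
#' * `dro_proportional_size` — adds `C * sqrt(n_k / N)`.
#' * `dro_marginal_baselined` — adds the estimated negative marginal entropy
#'   of the outcome, `q log q + (1 - q) log(1 - q)`, removing the
#'   incidence-driven component of the loss before groups are compared.
#' * `dro_metric` — replaces the loss in the lambda update by a metric
#'   `g(D_k, f)`; `"auc"` uses `1 - AUC` with strict pairwise comparisons,
#'   `"loss"` reproduces the unadjusted update.
#'
#' @param variant One of the six variants above.
#' @param eta Exponentiated-gradient learning rate (> 0 for DRO variants);
#'   the experiment grid is {1, 0.1, 0.01}.
#' @param C Size-adjustment constant (> 0; size variants only); grid
#'   {1, 0.1, 0.01}.
#' @param metric `"auc"` or `"loss"` (metric variant only).
#' @param entropy_source `"minibatch"` (stochastic estimate from the current
#'   minibatch) or `"precomputed"` (full-training-set incidences);
#'   marginal-baselined only.
#' @return An `objective_config` list.
#' @export
objective_config <- function(variant = c("erm", "dro_unadjusted",
                                         "dro_reciprocal_size",
                                         "dro_proportional_size",
                                         "dro_marginal_baselined",
                                         "dro_metric"),
                             eta = 1, C = 1,
                             metric = c("auc", "loss"),
                             entropy_source = c("minibatch", "precomputed")) {
  variant <- match.arg(variant)
  metric <- match.arg(metric)
  entropy_source <- match.arg(entropy_source)
  if (variant != "erm" && eta <= 0) {
    abort("configuration error: eta must be > 0 for DRO variants",
          class = "groupdro_config_error")
  }
  if (variant %in% c("dro_reciprocal_size", "dro_proportional_size") && C <= 0) {
    abort("configuration error: C must be > 0 for size-adjusted variants",
          class = "groupdro_config_error")
  }
  structure(list(variant = variant, eta = eta, C = C, metric = metric,
                 entropy_source = entropy_source),
            class = "objective_config")
}

#' Per-group cross-entropy losses
#'
#' Mean of `-(y log s + (1 - y) log(1 - s))` within each declared group.
#' Groups with no samples (possible in a pooled minibatch) are flagged
#' absent, never imputed.
#'
#' @param scores Numeric scores in (0, 1); clipped at `eps` before the log.
#' @param outcomes Binary 0/1 vector.
#' @param groups Group labels.
#' @param levels Group vocabulary (order fixes the output order); default
#'   sorted unique labels.
#' @param eps Clipping constant.
#' @return Tibble with columns `group`, `n`, `loss` (`NA` when absent) and
#'   `present`.
#' @export
group_losses <- function(scores, outcomes, groups, levels = NULL,
                         eps = 1e-7) {
  stopifnot(length(scores) == length(outcomes),
            length(scores) == length(groups))
  levels <- levels %||% sort(unique(as.character(groups)))
  codes <- group_codes(groups, levels)
  s <- clip_prob(scores, eps)
  li <- bce(outcomes, s)
  n <- tabulate(codes, nbins = length(levels))
  tot <- vapply(seq_along(levels),
                function(k) sum(li[codes == k]), numeric(1))
  tibble::tibble(group = levels, n = n,
                 loss = ifelse(n > 0, tot / pmax(n, 1), NA_real_),
                 present = n > 0)
}

#' Additive adjustment vector for the exponentiated-gradient update
#'
#' @param config An [objective_config()].
#' @param stats A [group_summary()] tibble of the training cohort (supplies
#'   `n_k`, `p_k` and precomputed incidences).
#' @param minibatch_outcomes,minibatch_groups Outcome / group vectors of the
#'   current minibatch, required when the marginal-baselined variant uses
#'   `entropy_source = "minibatch"`.
#' @param eps Incidence clipping constant for the entropy formula (degenerate
#'   minibatch incidences of 0 or 1 are clipped before taking logs).
#' @return Numeric vector `c_k` of length K in vocabulary order (zero for
#'   the unadjusted, ERM and metric variants; a group absent from the
#'   minibatch gets 0 under the minibatch entropy source — its update is
#'   masked anyway).
#' @export
compute_adjustment <- function(config, stats, minibatch_outcomes = NULL,
                               minibatch_groups = NULL, eps = 1e-7) {
  K <- nrow(stats)
  switch(config$variant,
    dro_reciprocal_size = {
      if (any(stats$fraction == 0)) {
        abort("adjustment error: p_k = 0 under the reciprocal size adjustment",
              class = "groupdro_config_error")
      }
      config$C / stats$fraction
    },
    dro_proportional_size = config$C * sqrt(stats$fraction),
    dro_marginal_baselined = {
      q <- if (config$entropy_source == "minibatch") {
        stopifnot(!is.null(minibatch_outcomes), !is.null(minibatch_groups))
        codes <- group_codes(minibatch_groups, stats$group)
        nk <- tabulate(codes, nbins = K)
        vapply(seq_len(K), function(k) {
          if (nk[k] == 0) return(NA_real_)
          mean(minibatch_outcomes[codes == k])
        }, numeric(1))
      } else {
        stats$incidence
      }
      q <- clip_prob(q, eps)
      ck <- q * log(q) + (1 - q) * log1p(-q)
      ck[is.na(ck)] <- 0
      ck
    },
    rep(0, K)
  )
}

#' Exponentiated-gradient update of the group weights
#'
#' `lambda_k <- lambda_k * exp(eta * badness_k)`, renormalized to the
#' simplex. `badness` is `l_k + c_k` for the loss-driven variants or
#' `g(D_k, f)` for the metric variant. Groups absent from the minibatch keep
#' their pre-update unnormalized mass (badness treated as 0) and participate
#' in the renormalization. A constant shift of `badness` leaves the result
#' unchanged only when all groups are present.
#'
#' @param lambda Current simplex vector of length K.
#' @param badness Numeric vector of length K; must be finite wherever
#'   `present` is `TRUE`.
#' @param eta Positive learning rate.
#' @param present Logical mask of groups represented in the minibatch.
#' @return Updated simplex vector (non-negative, sums to 1 within 1e-9).
#' @examples
#' update_weights(c(0.5, 0.5), badness = c(1, 0), eta = 1)
#' # -> (e, 1) / (e + 1)
#' @export
update_weights <- function(lambda, badness, eta,
                           present = rep(TRUE, length(lambda))) {
  stopifnot(length(lambda) == length(badness),
            length(present) == length(lambda), eta >= 0)
  if (any(!is.finite(badness[present]))) {
    abort("non-finite badness in weight update")
  }
  b <- ifelse(present, badness, 0)
  z <- eta * b
  w <- lambda * exp(z - max(z))   # uniform rescaling cancels on the simplex
  w / sum(w)
}

#' Strict-comparison AUC complement used by the metric-steered update
#'
#' `g = 1 - (1 / (n1 n0)) * sum over (positive, negative) pairs of
#' 1[s_pos > s_neg]`: ties contribute nothing to the AUC sum, so tied scores
#' increase g. This strictness is intentional and distinct from the
#' evaluation-side [auc()], which counts ties as 1/2.
#'
#' @param scores Numeric score vector.
#' @param outcomes Binary 0/1 vector.
#' @return `g` in `[0, 1]`; `NA` when only one class is present (the
#'   training loop skips that group's update).
#' @export
g_auc <- function(scores, outcomes) {
  stopifnot(length(scores) == length(outcomes))
  pos <- scores[outcomes == 1]
  neg <- scores[outcomes == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  concordant <- sum(findInterval(pos, sort(neg), left.open = TRUE))
  1 - concordant / (length(pos) * length(neg))
}

#' Lambda-weighted loss
#'
#' The scalar the model parameters descend: `sum over present groups of
#' lambda_k * l_k` (no renormalization over the present set).
#'
#' @param lambda Simplex vector of length K.
#' @param losses Numeric per-group losses (`NA` for absent groups) or a
#'   [group_losses()] tibble.
#' @param present Logical mask; defaults to `!is.na(losses)`.
#' @return Scalar.
#' @export
weighted_loss <- function(lambda, losses, present = NULL) {
  if (is.data.frame(losses)) {
    present <- present %||% losses$present
    losses <- losses$loss
  }
  present <- present %||% !is.na(losses)
  sum(lambda[present] * losses[present])
}
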