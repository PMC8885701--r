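#' Configure the minibatch training loop
#'
#' Defaults mirror the experiment design: up to 150 epochs of 100
#' minibatches of size 512, stopping when the development-set criterion has
#' not improved for 25 consecutive epochs. ("Iteration" and "epoch" both
#' denote one pass of `batches_per_epoch` minibatches.)
#'
#' @param max_epochs Maximum number of epochs (default 150).
#' @param batches_per_epoch Minibatches per epoch (default 100).
#' @param batch_size Minibatch size (default 512).
#' @param patience Epochs without improvement before stopping (default 25).
#' @param criterion Early-stopping criterion on the development fold, lower
#'   is better: `"population_loss"`, `"worst_group_loss"`,
#'   `"worst_group_auc"` (negated minimum group AUC) or
#'   `"weighted_objective"` (the DRO objective value, `sum lambda_k l_k`).
#' @param sampler `"pooled"` or `"balanced"`.
#' @param seed Seed for the sampler and dropout streams.
#' @return A `train_config` list.
#' @export
train_config <- function(max_epochs = 150L, batches_per_epoch = 100L,
                         batch_size = 512L, patience = 25L,
                         criterion = c("population_loss", "worst_group_loss",
                                       "worst_group_auc",
                                       "weighted_objective"),
                         sampler = c("pooled", "balanced"), seed = 1L) {
  criterion <- match.arg(criterion)
  sampler <- match.arg(sampler)
  stopifnot(patience >= 1, patience <= max_epochs)
  structure(list(max_epochs = as.integer(max_epochs),
                 batches_per_epoch = as.integer(batches_per_epoch),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 criterion = criterion, sampler = sampler,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Early-stopping / selection criterion value (lower is better)
#'
#' @param criterion Criterion name; see [train_config()].
#' @param scores,outcomes,groups Predictions on the development fold.
#' @param levels Group vocabulary.
#' @param lambda Current group weights (required for
#'   `"weighted_objective"`).
#' @return Scalar criterion value.
#' @export
criterion_value <- function(criterion, scores, outcomes, groups,
                            levels = NULL, lambda = NULL) {
  levels <- levels %||% sort(unique(as.character(groups)))
  switch(criterion,
    population_loss = mean_loss(scores, outcomes),
    worst_group_loss = {
      gl <- group_losses(scores, outcomes, groups, levels)
      max(gl$loss[gl$present])
    },
    worst_group_auc = {
      codes <- group_codes(groups, levels)
      aucs <- vapply(seq_along(levels), function(k) {
        sel <- codes == k
        if (!any(sel)) return(NA_real_)
        auc(scores[sel], outcomes[sel])
      }, numeric(1))
      present <- !is.na(aucs)
      if (!any(present)) abort("no group with both outcome classes on dev")
      -min(aucs[present])
    },
    weighted_objective = {
      stopifnot(!is.null(lambda))
      gl <- group_losses(scores, outcomes, groups, levels)
      weighted_loss(lambda, gl)
    },
    abort(paste0("unknown criterion: ", criterion))
  )
}

#' Train a model with ERM or a GroupDRO objective
#'
#' Alternates, per minibatch, an exponentiated-gradient ascent step on the
#' subpopulation weights (DRO variants; the badness is the adjusted group
#' loss or the steering metric computed on that minibatch) with an Adam
#' descent step on the model parameters targeting the lambda-weighted
#' cross-entropy (pooled mean for ERM). The development criterion is
#' evaluated once per epoch with dropout disabled; the best snapshot seen is
#' restored at the end. Lambda persists across epochs. Groups absent from a
#' minibatch, or whose steering metric is undefined there (single-class AUC
#' sample), keep their weight for that step.
#'
#' @param model A [build_model()] model (its spec carries the Adam learning
#'   rate; the DRO `eta` is separate and only scales the lambda update).
#' @param objective An [objective_config()].
#' @param train_part,dev_part Cohorts; the dev part drives early stopping.
#' @param config A [train_config()].
#' @return A `dro_fit`: `model` (best snapshot), `history` (per-epoch tibble
#'   of criterion and per-group dev losses, plus the lambda trajectory),
#'   `lambda` (final weights), `best_epoch`, `stopped_epoch`, `best_value`.
#' @export
train_model <- function(model, objective, train_part, dev_part, config) {
  stopifnot(inherits(model, "dro_model"),
            inherits(objective, "objective_config"),
            inherits(config, "train_config"))
  lv <- group_levels(train_part)
  K <- length(lv)
  if (config$criterion == "worst_group_auc") {
    dcodes <- group_codes(dev_part$group, lv)
    ok <- vapply(seq_len(K), function(k) {
      ys <- dev_part$outcome[dcodes == k]
      length(unique(ys)) == 2
    }, logical(1))
    if (!any(ok)) {
      abort("worst_group_auc criterion needs a dev group with both classes",
            class = "groupdro_config_error")
    }
    if (!all(ok)) {
      abort(paste0("worst_group_auc criterion: single-class dev group(s): ",
                   paste(lv[!ok], collapse = ", ")),
            class = "groupdro_config_error")
    }
  }

  X <- feature_matrix(train_part)
  y <- train_part$outcome
  codes <- group_codes(train_part$group, lv)
  Xdev <- feature_matrix(dev_part)
  stats <- group_summary(train_part)
  is_dro <- objective$variant != "erm"
  # static adjustments (size-based / precomputed entropy) need no minibatch
  static_adj <- if (is_dro &&
                    !(objective$variant == "dro_marginal_baselined" &&
                      objective$entropy_source == "minibatch")) {
    compute_adjustment(objective, stats)
  }

  plan <- batch_plan(config$batch_size, config$batches_per_epoch,
                     mode = config$sampler,
                     seed = derive_seed(config$seed, "sampler"))
  lambda <- rep(1 / K, K)
  adam <- adam_init(model)
  t_step <- 0L
  best_value <- Inf
  best_model <- model
  best_epoch <- 0L
  since_improved <- 0L
  hist <- vector("list", config$max_epochs)

  for (epoch in seq_len(config$max_epochs)) {
    batches <- make_batches(train_part, plan, epoch)
    drop_seed <- derive_seed(config$seed, "dropout", epoch)
    withr::with_seed(drop_seed, {
      for (bi in seq_along(batches)) {
        idx <- batches[[bi]]
        Xb <- X[idx, , drop = FALSE]
        yb <- y[idx]
        cb <- codes[idx]
        fwd <- model_forward(model, Xb, train = TRUE)
        sb <- clip_prob(fwd$score)
        nb <- tabulate(cb, nbins = K)
        present <- nb > 0
        if (is_dro) {
          lb <- vapply(seq_len(K), function(k) {
            if (!present[k]) return(NA_real_)
            mean(bce(yb[cb == k], sb[cb == k]))
          }, numeric(1))
          badness <- if (objective$variant == "dro_metric") {
            if (objective$metric == "auc") {
              vapply(seq_len(K), function(k) {
                if (!present[k]) return(NA_real_)
                g_auc(sb[cb == k], yb[cb == k])
              }, numeric(1))
            } else lb
          } else {
            adj <- static_adj %||%
              compute_adjustment(objective, stats,
                                 minibatch_outcomes = yb,
                                 minibatch_groups = train_part$group[idx])
            lb + adj
          }
          mask <- present & !is.na(badness)
          if (any(mask)) {
            lambda <- update_weights(lambda, badness, objective$eta, mask)
          }
          # per-sample weights realizing sum_k lambda_k * mean-group-loss
          w <- numeric(length(idx))
          for (k in which(present)) w[cb == k] <- lambda[k] / nb[k]
        } else {
          w <- rep(1 / length(idx), length(idx))
        }
        grads <- model_backward(model, fwd, yb, w)
        t_step <- t_step + 1L
        upd <- adam_step(model, grads, adam, t_step,
                         model$spec$learning_rate)
        model <- upd$model
        adam <- upd$state
      }
    })

    sdev <- model_forward(model, Xdev, train = FALSE)$score
    crit <- criterion_value(config$criterion, sdev, dev_part$outcome,
                            dev_part$group, lv, lambda = lambda)
    gl_dev <- group_losses(sdev, dev_part$outcome, dev_part$group, lv)
    hist[[epoch]] <- c(list(epoch = epoch, criterion = crit),
                       setNames(as.list(gl_dev$loss),
                                paste0("dev_loss_", lv)),
                       setNames(as.list(lambda), paste0("lambda_", lv)))

    if (crit < best_value - 1e-6) {   # strict improvement with tolerance
      best_value <- crit
      best_model <- model
      best_epoch <- epoch
      since_improved <- 0L
    } else {
      since_improved <- since_improved + 1L
    }
    if (since_improved >= config$patience) break
  }

  structure(list(
    model = best_model,
    lambda = setNames(lambda, lv),
    history = dplyr::bind_rows(lapply(hist[!vapply(hist, is.null, logical(1))],
                                      tibble::as_tibble)),
    best_epoch = best_epoch,
    stopped_epoch = epoch,
    best_value = best_value,
    objective = objective,
    config = config
  ), class = "dro_fit")
}

#' @export
print.dro_fit <- function(x, ...) {
  cat("<dro_fit>", x$objective$variant,
      "| best epoch", x$best_epoch, "of", x$stopped_epoch,
      "| best", x$config$criterion, "=", signif(x$best_value, 5), "\n")
  invisible(x)
}

#' Tidy the training history of a fit
#'
#' @param x A `dro_fit`.
#' @param ... Unused.
#' @return Long tibble with columns `epoch`, `series` (criterion, per-group
#'   dev loss, lambda entries) and `value`.
#' @method tidy dro_fit
#' @export
tidy.dro_fit <- function(x, ...) {
  tidyr::pivot_longer(x$history, -"epoch",
                      names_to = "series", values_to = "value")
}

#' One-row summary of a fit
#'
#' @param x A `dro_fit`.
#' @param ... Unused.
#' @return Tibble with the objective variant, criterion, best value and
#'   stopping epochs.
#' @method glance dro_fit
#' @export
glance.dro_fit <- function(x, ...) {
  tibble::tibble(variant = x$objective$variant,
                 criterion = x$config$criterion,
                 best_value = x$best_value,
                 best_epoch = x$best_epoch,
                 stopped_epoch = x$stopped_epoch)
}
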