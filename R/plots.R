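#' Forest plot of a disaggregated evaluation report
#'
#' Point estimates with bootstrap intervals per population, faceted by
#' metric. With `relative = TRUE` (and a report built against a reference),
#' plots the paired differences instead, with a dashed zero line.
#'
#' @param object A [bootstrap_report()] result.
#' @param relative Plot paired differences versus the reference.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dro_eval_report
#' @export
autoplot.dro_eval_report <- function(object, relative = FALSE, ...) {
  df <- tibble::as_tibble(as.data.frame(object))
  if (relative) {
    stopifnot("delta" %in% names(df))
    df$estimate <- df$delta; df$ci_low <- df$delta_low
    df$ci_high <- df$delta_high
  }
  df$population <- factor(df$population, levels = rev(unique(df$population)))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate,
                                        y = .data$population)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::facet_wrap(~metric, scales = "free_x") +
    ggplot2::labs(x = if (relative) "difference vs. reference" else "estimate",
                  y = NULL) +
    ggplot2::theme_minimal()
  if (relative) {
    p <- p + ggplot2::geom_vline(xintercept = 0, linetype = "dashed")
  }
  p
}

#' Training trajectory of a fit
#'
#' Development-set criterion, per-group dev losses and the group-weight
#' (lambda) trajectory over epochs.
#'
#' @param object A [train_model()] fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dro_fit
#' @export
autoplot.dro_fit <- function(object, ...) {
  df <- tidy(object)
  df$panel <- dplyr::case_when(
    df$series == "criterion" ~ "criterion",
    grepl("^lambda_", df$series) ~ "lambda",
    TRUE ~ "dev loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch,
                        linetype = "dotted") +
    ggplot2::facet_wrap(~panel, scales = "free_y", ncol = 1) +
    ggplot2::theme_minimal()
}

#' Group-weight trajectory of a DRO fit
#'
#' @param fit A [train_model()] fit of a DRO variant.
#' @return A ggplot object showing each subpopulation's lambda over epochs.
#' @export
plot_lambda <- function(fit) {
  df <- tidy(fit)
  df <- df[grepl("^lambda_", df$series), ]
  df$group <- sub("^lambda_", "", df$series)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "group weight (lambda)") +
    ggplot2::theme_minimal()
}
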