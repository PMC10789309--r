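# Broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname tidy_methods
#' @name tidy_methods
#' @title Tidy and glance methods for fitted objects
#' @description `tidy()` returns per-epoch training curves (for checkpoints
#'   and classifiers) or per-metric rows (for pipeline runs); `glance()`
#'   returns a one-row summary.
#' @param x A fitted object.
#' @param ... Unused.
NULL

#' @rdname tidy_methods
#' @export
tidy.ssl_checkpoint <- function(x, ...) x$loss_curve

#' @rdname tidy_methods
#' @export
glance.ssl_checkpoint <- function(x, ...) {
  lc <- x$loss_curve
  tibble::tibble(epochs = nrow(lc), first_loss = lc$loss[1],
                 final_loss = lc$loss[nrow(lc)], n_params = x$n_params,
                 n = x$n, dim = x$model_spec$dim,
                 views = paste(x$views, collapse = "+"))
}

#' @rdname tidy_methods
#' @export
tidy.rbp_classifier <- function(x, ...) x$loss_curve

#' @rdname tidy_methods
#' @export
glance.rbp_classifier <- function(x, ...) {
  lc <- x$loss_curve
  tibble::tibble(epochs = nrow(lc), first_loss = lc$loss[1],
                 final_loss = lc$loss[nrow(lc)], n_train = x$n_train,
                 pretrained = x$pretrained, n_params = x$n_params)
}

#' @rdname tidy_methods
#' @export
tidy.pipeline_run <- function(x, ...) {
  tidyr::pivot_longer(x$metrics[, c("auc", "acc", "precision", "recall")],
                      dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' @rdname tidy_methods
#' @export
glance.pipeline_run <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(ratio = sprintf("%d:%d", x$ratio[1], x$ratio[2]),
                                  seed = x$seed, pretrained = x$pretrained),
                   x$metrics)
}

loss_curve_plot <- function(curve, title) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(title = title, x = "epoch", y = "training loss") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot_methods
#' @name autoplot_methods
#' @title Plots for training curves and experiment results
#' @description Loss curves for checkpoints/classifiers, ROC for pipeline
#'   runs, metric-vs-ratio profiles for sweeps, and per-arm AUC for ablations.
#' @param object A result object.
#' @param ... Unused.
NULL

#' @rdname autoplot_methods
#' @export
autoplot.ssl_checkpoint <- function(object, ...) {
  loss_curve_plot(object$loss_curve, "Cross-view pretraining loss")
}

#' @rdname autoplot_methods
#' @export
autoplot.rbp_classifier <- function(object, ...) {
  loss_curve_plot(object$loss_curve, "Fine-tuning loss")
}

#' @rdname autoplot_methods
#' @export
autoplot.pipeline_run <- function(object, ...) {
  d <- object$predictions[order(-object$predictions$p_bound), ]
  roc <- tibble::tibble(
    fpr = c(0, cumsum(d$label == 0) / max(1, sum(d$label == 0))),
    tpr = c(0, cumsum(d$label == 1) / max(1, sum(d$label == 1))))
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey") +
    ggplot2::labs(title = sprintf("ROC (AUC = %.3f)", object$metrics$auc),
                  x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot_methods
#' @export
autoplot.ratio_sweep <- function(object, ...) {
  d <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "ratio", "auc", "acc",
                  "precision", "recall"),
    -"ratio", names_to = "metric", values_to = "value")
  d$ratio <- factor(d$ratio, levels = unique(object$ratio))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ratio, y = .data$value,
                                  group = .data$metric,
                                  colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(title = "Performance across train:test ratios",
                  x = "train:test ratio", y = "value") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot_methods
#' @export
autoplot.ablation_result <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$arm, y = .data$auc)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, height = 0) +
    ggplot2::labs(title = "Test AUC with and without self-supervised pretraining",
                  x = NULL, y = "AUC") +
    ggplot2::theme_minimal()
}
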