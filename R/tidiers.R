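# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a cross-validation result into long format
#'
#' @param x A `cv_result` from [repeated_kfold_cv()].
#' @param ... Unused.
#' @return Tibble: `iteration`, `fold`, `metric`, `value`.
#' @export
tidy.cv_result <- function(x, ...) {
  metric_cols <- c("balanced_accuracy", "precision", "sensitivity",
                   "specificity", "mcc", "f1")
  tidyr::pivot_longer(
    tibble::as_tibble(x)[, c("iteration", "fold", metric_cols)],
    dplyr::all_of(metric_cols), names_to = "metric", values_to = "value"
  )
}

#' One-row cross-validation summary
#'
#' @param x A `cv_result`. @param ... Unused.
#' @return One-row tibble of metric means (plus `n_folds`).
#' @export
glance.cv_result <- function(x, ...) {
  s <- attr(x, "summary")
  out <- tidyr::pivot_wider(s[, c("metric", "mean")], names_from = "metric",
                            values_from = "mean")
  out$n_folds <- nrow(x)
  out
}

#' Box plot of cross-validated metrics
#'
#' @param object A `cv_result`. @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cv_result <- function(object, ...) {
  d <- tidy.cv_result(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "score",
                  title = "Cross-validated performance") +
    ggplot2::theme_minimal()
}

#' @export
tidy.importance_result <- function(x, ...) tibble::as_tibble(x)

#' Bar chart of permutation importances
#'
#' @param object An `importance_result` from [permutation_importance()].
#' @param top_n Features shown (default 20). @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.importance_result <- function(object, top_n = 20, ...) {
  d <- utils::head(tibble::as_tibble(object), top_n)
  d$feature <- factor(d$feature, levels = rev(d$feature))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$importance, y = .data$feature)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$importance - .data$sd,
                   xmax = .data$importance + .data$sd), height = 0.3) +
    ggplot2::labs(y = NULL, x = "importance (metric drop)",
                  title = "Permutation importance") +
    ggplot2::theme_minimal()
}

#' @export
tidy.shap_result <- function(x, ...) tibble::as_tibble(x)

#' Mean absolute Shapley attribution per feature
#'
#' @param object A `shap_result` from [shap_summary()].
#' @param top_n Features shown (default 20). @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.shap_result <- function(object, top_n = 20, ...) {
  d <- tibble::as_tibble(object) |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(mean_abs = mean(abs(.data$value)), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_abs)) |>
    utils::head(top_n)
  d$feature <- factor(d$feature, levels = rev(d$feature))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_abs, y = .data$feature)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::labs(x = "mean |Shapley value|", y = NULL,
                  title = "Shapley feature attribution") +
    ggplot2::theme_minimal()
}

#' One-row model summary
#'
#' @param x A `qsar_model`. @param ... Unused.
#' @return Tibble: family, encoders, trained flag, epochs (networks).
#' @export
glance.qsar_model <- function(x, ...) {
  tibble::tibble(
    family = x$spec$family,
    encoders = paste(x$spec$encoders, collapse = "+"),
    trained = x$trained,
    epochs = if (!is.null(x$history)) nrow(x$history) else NA_integer_,
    final_val_loss = if (!is.null(x$history)) {
      utils::tail(x$history$val_loss, 1)
    } else NA_real_
  )
}

#' Training-history curves of a network model
#'
#' @param object A trained network `qsar_model`. @param ... Unused.
#' @return A ggplot of training and validation loss by epoch.
#' @export
autoplot.qsar_model <- function(object, ...) {
  if (is.null(object$history)) {
    stop("autoplot.qsar_model: no training history (baseline family?)")
  }
  d <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                           names_to = "series", values_to = "loss")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = paste("Training history:", object$spec$family)) +
    ggplot2::theme_minimal()
}

#' @export
tidy.pipeline_result <- function(x, ...) tibble::as_tibble(x$metrics)

#' Metric-versus-training-size curves for a split series
#'
#' @param object A `pipeline_result` run over several test fractions.
#' @param metric Metric column to plot (default balanced accuracy).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pipeline_result <- function(object, metric = "balanced_accuracy", ...) {
  d <- object$metrics[object$metrics$partition == "test", , drop = FALSE]
  d$train_fraction <- 1 - d$split
  ggplot2::ggplot(d, ggplot2::aes(x = .data$train_fraction,
                                  y = .data[[metric]],
                                  colour = .data$family)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "training fraction", y = metric,
                  title = "Performance vs training-set size") +
    ggplot2::theme_minimal()
}
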