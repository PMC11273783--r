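#' Tidy a model report
#'
#' One row per outer fold: the fold AUC, chosen hyperparameters, and number
#' of selected features.
#'
#' @param x A `model_report` from [nested_cv()].
#' @param ... Unused.
#' @return Tibble with columns `fold`, `auc`, `C`, `gamma`, `n_features`.
#' @export
tidy.model_report <- function(x, ...) {
  dplyr::select(x$per_fold, "fold", "auc", "C", "gamma", "n_features")
}

#' One-row summary of a model report
#'
#' @param x A `model_report` from [nested_cv()].
#' @param ... Unused.
#' @return One-row tibble: kernel, mean/sd per-fold AUC, pooled AUC, and
#'   the pooled confusion metrics.
#' @export
glance.model_report <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(
      kernel = x$kernel, mean_auc = x$mean_auc,
      sd_auc = x$sd_auc, pooled_auc = x$pooled_auc
    ),
    dplyr::select(x$metrics, -"undefined")
  )
}

# ROC points (FPR, TPR) from pooled decision scores
roc_points <- function(labels, scores) {
  ord <- order(-scores)
  labels <- labels[ord]
  tibble::tibble(
    fpr = c(0, cumsum(labels == 0) / max(1, sum(labels == 0))),
    tpr = c(0, cumsum(labels == 1) / max(1, sum(labels == 1)))
  )
}

#' ROC curve(s) for one or more model reports
#'
#' Plots the pooled-score ROC curve of each report with its mean per-fold
#' AUC in the legend. `autoplot()` on a single `model_report` delegates
#' here.
#'
#' @param reports A `model_report`, or a named list of them (e.g.
#'   `list(linear = ..., rbf = ...)`).
#' @return A ggplot object.
#' @export
plot_roc <- function(reports) {
  if (inherits(reports, "model_report")) {
    reports <- setNames(list(reports), reports$kernel)
  }
  df <- dplyr::bind_rows(lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    dplyr::mutate(
      roc_points(r$predictions$label, r$predictions$score),
      model = sprintf("%s (AUC %.3f)", nm, r$mean_auc)
    )
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$fpr, .data$tpr, color = .data$model)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, color = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      color = NULL, title = "Nested-CV ROC (pooled decision scores)"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_roc
#' @param object A `model_report`.
#' @param ... Unused.
#' @export
autoplot.model_report <- function(object, ...) {
  plot_roc(object)
}

#' Confusion-matrix plot
#'
#' @param report A `model_report`.
#' @return A ggplot object.
#' @export
plot_confusion <- function(report) {
  m <- report$metrics
  df <- tibble::tibble(
    truth = factor(c("effective", "effective", "invalid", "invalid"),
      levels = c("effective", "invalid")
    ),
    predicted = factor(c("effective", "invalid", "effective", "invalid"),
      levels = c("effective", "invalid")
    ),
    n = c(m$tp, m$fn, m$fp, m$tn)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$truth, fill = .data$n)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 6) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7fb8") +
    ggplot2::labs(
      x = "Predicted", y = "True",
      title = sprintf("%s SVM confusion matrix", report$kernel)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Feature-correlation heatmap
#'
#' @param corr_report Output of [feature_correlation_report()].
#' @param max_features Downsample to at most this many columns for display.
#'   Default 400.
#' @return A ggplot object.
#' @export
plot_correlation_heatmap <- function(corr_report, max_features = 400L) {
  cm <- corr_report$cor
  if (ncol(cm) > max_features) {
    idx <- round(seq(1L, ncol(cm), length.out = max_features))
    cm <- cm[idx, idx]
  }
  df <- tidyr::expand_grid(
    i = seq_len(nrow(cm)), j = seq_len(ncol(cm))
  )
  df$r <- cm[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(.data$j, .data$i, fill = .data$r)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(
      low = "#4575b4", mid = "white", high = "#1a9850", limits = c(-1, 1)
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(
      x = NULL, y = NULL, fill = "PCC",
      title = "Feature correlation (image | nuclei | cytoplasm)"
    ) +
    ggplot2::theme_minimal()
}
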