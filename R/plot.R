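#' Plot an evaluation report
#'
#' `type = "roc"` draws the pooled out-of-fold ROC curve; `type = "folds"`
#' draws per-fold accuracy with its 95% Wald interval and the unweighted
#' mean as a dashed line.
#'
#' @param object an `eval_report`.
#' @param type `"roc"` or `"folds"`.
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.eval_report <- function(object, type = c("roc", "folds"), ...) {
  type <- match.arg(type)
  if (type == "roc") {
    auc <- rank_auc(object$pooled$y_true, object$pooled$p_asd)
    ggplot(object$pooled_roc, aes(x = .data$fpr, y = .data$tpr)) +
      geom_line(colour = "#2c7fb8", linewidth = 0.8) +
      geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
      labs(x = "False positive rate", y = "True positive rate",
           title = sprintf("Pooled ROC (AUC = %.3f)", auc)) +
      theme_minimal()
  } else {
    df <- object$folds
    ggplot(df, aes(x = .data$fold_label, y = .data$accuracy)) +
      geom_point(size = 2) +
      geom_errorbar(aes(ymin = .data$accuracy - .data$ci_halfwidth,
                        ymax = .data$accuracy + .data$ci_halfwidth),
                    width = 0.2) +
      geom_hline(yintercept = object$mean_row$accuracy, linetype = "dashed",
                 colour = "#d95f02") +
      labs(x = "Fold", y = "Accuracy",
           title = "Per-fold accuracy (95% Wald interval)") +
      theme_minimal()
  }
}

#' Plot a saliency map as an edge heatmap
#'
#' @param object a `saliency_map`.
#' @param ... ignored.
#' @return a ggplot object (signed gradient, diverging palette).
#' @export
autoplot.saliency_map <- function(object, ...) {
  g <- object$gradient
  df <- tibble(
    row = rep(seq_len(nrow(g)), times = ncol(g)),
    col = rep(seq_len(ncol(g)), each = nrow(g)),
    gradient = as.vector(g)
  )
  ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$gradient)) +
    geom_raster() +
    scale_fill_gradient2(low = "#313695", mid = "white", high = "#a50026") +
    labs(x = "ROI", y = "ROI", fill = "d score / d input",
         title = paste0("Input-gradient saliency (class ", object$class_index,
                        ")")) +
    theme_minimal()
}

#' Plot the top ROI importance scores
#'
#' @param object a `roi_importance` tibble from [roi_scores()].
#' @param k number of top ROIs to show; default 20.
#' @param ... ignored.
#' @return a ggplot bar chart.
#' @export
autoplot.roi_importance <- function(object, k = 20L, ...) {
  df <- utils::head(object, min(k, nrow(object)))
  df$roi_label <- factor(df$roi_label, levels = rev(df$roi_label))
  ggplot(df, aes(x = .data$roi_label, y = .data$score)) +
    geom_col(fill = "#2c7fb8") +
    coord_flip() +
    labs(x = NULL, y = "Importance score",
         title = paste0("Top ", nrow(df), " ROIs by saliency")) +
    theme_minimal()
}
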