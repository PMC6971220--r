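#' Input-gradient class saliency map
#'
#' Computes the exact analytic gradient of the pre-softmax class score with
#' respect to every entry of the input connectome, with the network in
#' inference mode (dropout disabled). Positive entries mark connections whose
#' strengthening increases the class score.
#'
#' @param model a `conncnn_model`.
#' @param x an R x R connectome.
#' @param class_index class whose score is differentiated: 1 = ASD (default),
#'   0 = control.
#' @param subject_id optional id carried in the result.
#' @return a `saliency_map`: list with `gradient` (R x R matrix),
#'   `class_index` and `subject_id`.
#' @export
input_gradient <- function(model, x, class_index = 1L, subject_id = NULL) {
  stopifnot(inherits(model, "conncnn_model"))
  cfg <- model$config
  check_input_shape(x, cfg$n_rois)
  class_index <- as.integer(class_index)
  if (class_index < 0L || class_index >= cfg$n_classes) {
    abort(paste0("class_index must be in 0..", cfg$n_classes - 1L),
          class = "conncnn_config_error")
  }
  plist <- lapply(cfg$branch_lengths, function(k) conv_patches(x, k))
  fwd <- nn_forward(model, plist, 1L, cache = TRUE)
  g <- nn_backward(model, plist, 1L, fwd, score_class = class_index,
                   input_grad = TRUE)
  grad <- g$input
  dimnames(grad) <- dimnames(x)
  structure(list(gradient = grad, class_index = class_index,
                 subject_id = subject_id),
            class = "saliency_map")
}

#' @export
print.saliency_map <- function(x, ...) {
  cat("<saliency_map> class", x$class_index,
      if (!is.null(x$subject_id)) paste0("(subject ", x$subject_id, ")"),
      "- range [", format(min(x$gradient), digits = 3), ",",
      format(max(x$gradient), digits = 3), "]\n")
  invisible(x)
}

#' Per-ROI importance scores from a saliency map
#'
#' Aggregates the signed R x R gradient into one non-negative score per ROI.
#' The default `sum_abs_row_col` credits ROI i with the total absolute
#' gradient over its row and column (counting the diagonal once):
#' `sum_j |g_ij| + sum_j |g_ji| - |g_ii|`. Ranking is descending by score,
#' ties broken by ascending ROI index.
#'
#' @param s a `saliency_map`, or a plain R x R gradient matrix.
#' @param aggregation `"sum_abs_row_col"` (default), `"max_abs"` or
#'   `"mean_abs"`.
#' @param roi_labels optional labels; default `C1 ... CR`.
#' @return a `roi_importance` tibble: `roi`, `roi_label`, `score`, `rank`,
#'   sorted by rank.
#' @export
roi_scores <- function(s, aggregation = c("sum_abs_row_col", "max_abs",
                                          "mean_abs"),
                       roi_labels = NULL) {
  aggregation <- match.arg(aggregation)
  g <- if (inherits(s, "saliency_map")) s$gradient else s
  stopifnot(is.matrix(g), nrow(g) == ncol(g))
  a <- abs(g)
  score <- switch(aggregation,
    sum_abs_row_col = rowSums(a) + colSums(a) - diag(a),
    max_abs = pmax(apply(a, 1L, max), apply(a, 2L, max)),
    mean_abs = (rowSums(a) + colSums(a) - diag(a)) / (2 * nrow(a) - 1)
  )
  R <- nrow(g)
  labels <- roi_labels %||% rownames(g) %||% paste0("C", seq_len(R))
  ord <- order(-score, seq_len(R))
  out <- tibble(roi = seq_len(R), roi_label = labels, score = unname(score))
  out$rank <- NA_integer_
  out$rank[ord] <- seq_len(R)
  out <- arrange(out, .data$rank)
  class(out) <- c("roi_importance", class(out))
  out
}

#' Top-k ROIs by importance
#'
#' @param imp a `roi_importance` tibble from [roi_scores()].
#' @param k how many ROIs to return (`1 <= k <= R`).
#' @return the first `k` rows of the ranking (`roi_label`, `score`, `rank`).
#' @export
top_rois <- function(imp, k) {
  stopifnot(inherits(imp, "roi_importance"))
  k <- as.integer(k)
  if (k < 1L || k > nrow(imp)) {
    abort(paste0("k must be in 1..", nrow(imp)), class = "conncnn_config_error")
  }
  imp[seq_len(k), c("roi_label", "score", "rank", "roi")]
}

#' Cohort-level saliency
#'
#' Averages per-subject absolute input-gradient maps over a subset of
#' subjects — by default the correctly classified ASD subjects, the cohort
#' whose shared discriminative pattern the map is meant to expose — and
#' returns the averaged map. Feed the result to [roi_scores()] for a
#' cohort-level ROI ranking.
#'
#' @param model a trained `conncnn_model`.
#' @param connectomes list of connectomes.
#' @param labels subject labels aligned with `connectomes`.
#' @param subset `"correct_asd"` (default) or `"all"`.
#' @param class_index class score to differentiate; default 1 (ASD).
#' @return a `saliency_map` whose `gradient` is the mean absolute map; the
#'   subject count used is in attribute `"n_subjects"`.
#' @export
cohort_saliency <- function(model, connectomes, labels,
                            subset = c("correct_asd", "all"),
                            class_index = 1L) {
  subset <- match.arg(subset)
  y <- encode_labels(labels)
  use <- seq_along(connectomes)
  if (subset == "correct_asd") {
    probs <- predict_proba(model, connectomes)
    pred <- max.col(probs, ties.method = "first") - 1L
    use <- which(y == 1L & pred == 1L)
    if (length(use) == 0L) {
      warn("no correctly classified ASD subjects; falling back to all subjects")
      use <- seq_along(connectomes)
    }
  }
  acc <- NULL
  for (i in use) {
    g <- abs(input_gradient(model, connectomes[[i]], class_index)$gradient)
    acc <- if (is.null(acc)) g else acc + g
  }
  out <- structure(list(gradient = acc / length(use),
                        class_index = as.integer(class_index),
                        subject_id = NULL),
                   class = "saliency_map")
  attr(out, "n_subjects") <- length(use)
  out
}

#' Write per-ROI importance scores to CSV
#'
#' @param imp a `roi_importance` tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_roi_importance <- function(imp, path) {
  utils::write.csv(as.data.frame(imp[, c("roi_label", "score", "rank")]),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
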