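#' Stratified k-fold split plan
#'
#' Shuffles subjects within each diagnostic class (seeded) and deals them
#' round-robin to folds, so per-fold class counts are within one subject of
#' the global proportions. Deterministic given `seed`.
#'
#' @param labels class labels (factor/character `ASD`/`TC` or 0/1).
#' @param k number of folds; default 10.
#' @param seed integer seed.
#' @return a `split_plan` tibble with columns `fold_label`, `train`, `test`
#'   (list-columns of integer indices); attributes `scheme` and `seed`.
#' @export
stratified_kfold <- function(labels, k = 10L, seed = 1L) {
  y <- encode_labels(labels)
  k <- as.integer(k)
  if (k < 2L) abort("k must be at least 2", class = "conncnn_config_error")
  for (cls in unique(y)) {
    if (sum(y == cls) < k) {
      abort(paste0("class ", cls, " has fewer than k = ", k, " members"),
            class = "conncnn_data_error")
    }
  }
  assign_fold <- integer(length(y))
  with_seed(seed, {
    for (cls in sort(unique(y))) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      assign_fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds <- lapply(seq_len(k), function(f) {
    list(test = which(assign_fold == f), train = which(assign_fold != f))
  })
  plan <- tibble(
    fold_label = as.character(seq_len(k)),
    train = lapply(folds, `[[`, "train"),
    test = lapply(folds, `[[`, "test")
  )
  structure(plan, scheme = "kfold", seed = seed, class = c("split_plan", class(plan)))
}

#' Leave-site-out split plan
#'
#' One fold per distinct acquisition site: that site's subjects form the test
#' set and all remaining sites train. Folds are ordered lexicographically by
#' site abbreviation.
#'
#' @param site_ids character vector of site labels, one per subject.
#' @return a `split_plan` tibble (see [stratified_kfold()]).
#' @export
leave_site_out <- function(site_ids) {
  site_ids <- as.character(site_ids)
  sites <- sort(unique(site_ids))
  if (length(sites) < 2L) {
    abort("leave-site-out needs at least 2 distinct sites",
          class = "conncnn_data_error")
  }
  plan <- tibble(
    fold_label = sites,
    train = lapply(sites, function(s) which(site_ids != s)),
    test = lapply(sites, function(s) which(site_ids == s))
  )
  structure(plan, scheme = "leave_site_out", seed = NA_integer_,
            class = c("split_plan", class(plan)))
}

#' Half-width of the normal-approximation (Wald) confidence interval
#'
#' `z * sqrt(p * (1 - p) / n)` for an observed proportion `p` on `n` trials;
#' `z = 1.96` gives the 95% level.
#'
#' @param p observed proportion in `[0, 1]`.
#' @param n number of trials.
#' @param z normal quantile; default 1.96.
#' @return the CI half-width.
#' @export
wald_ci <- function(p, n, z = 1.96) {
  stopifnot(all(p >= 0 & p <= 1), all(n >= 1))
  z * sqrt(p * (1 - p) / n)
}

# Mann-Whitney rank AUC (equals the trapezoidal ROC area, ties by midrank)
rank_auc <- function(y, score) {
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics for one evaluation fold
#'
#' Predicted class is the argmax of the probability pair (for a plain
#' probability-of-ASD vector, the `threshold` is used instead). Sensitivity
#' is the recall of the ASD class, specificity the recall of the control
#' class, and the F-score the harmonic mean of precision and sensitivity for
#' the ASD class. AUC uses the rank (Mann-Whitney) formulation, identical to
#' the trapezoidal area under the ROC curve. If a class is absent from
#' `y_true`, metrics that require it are `NA`, not 0.
#'
#' @param y_true true labels (`ASD`/`TC` or 0/1).
#' @param y_prob a B x 2 probability matrix (column 2 = ASD) or a vector of
#'   ASD probabilities.
#' @param threshold decision threshold for the vector form; default 0.5.
#' @param fold_label optional label carried into the result.
#' @return a one-row `fold_result` tibble: `fold_label`, `n`, `accuracy`,
#'   `ci_halfwidth`, `sensitivity`, `specificity`, `f_score`, `auc`, and the
#'   confusion counts `tn`, `fp`, `fn`, `tp`.
#' @export
compute_metrics <- function(y_true, y_prob, threshold = 0.5,
                            fold_label = NA_character_) {
  y <- encode_labels(y_true)
  if (is.matrix(y_prob)) {
    stopifnot(nrow(y_prob) == length(y), ncol(y_prob) == 2L)
    p1 <- y_prob[, 2L]
    pred <- max.col(y_prob, ties.method = "first") - 1L
  } else {
    stopifnot(length(y_prob) == length(y))
    p1 <- y_prob
    pred <- as.integer(p1 >= threshold)
  }
  n <- length(y)
  stopifnot(n >= 1L)
  tp <- sum(y == 1L & pred == 1L); fn <- sum(y == 1L & pred == 0L)
  tn <- sum(y == 0L & pred == 0L); fp <- sum(y == 0L & pred == 1L)
  accuracy <- (tp + tn) / n
  sensitivity <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  specificity <- if (tn + fp > 0L) tn / (tn + fp) else NA_real_
  precision <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
  f_score <- if (!is.na(sensitivity) && !is.na(precision) &&
                 (precision + sensitivity) > 0) {
    2 * precision * sensitivity / (precision + sensitivity)
  } else if (!is.na(sensitivity) && !is.na(precision)) {
    0
  } else {
    NA_real_
  }
  out <- tibble(
    fold_label = fold_label, n = n,
    accuracy = accuracy,
    ci_halfwidth = wald_ci(accuracy, n),
    sensitivity = sensitivity, specificity = specificity,
    f_score = f_score, auc = rank_auc(y, p1),
    tn = tn, fp = fp, fn = fn, tp = tp
  )
  class(out) <- c("fold_result", class(out))
  out
}

#' ROC curve points from labels and scores
#'
#' Sweeps the decision threshold over all distinct scores; ties are grouped,
#' so the area under the polyline equals the rank AUC.
#'
#' @param y_true labels; @param score ASD probability or score.
#' @return a tibble of (`fpr`, `tpr`) points from (0,0) to (1,1).
#' @export
roc_points <- function(y_true, score) {
  y <- encode_labels(y_true)
  ord <- order(score, decreasing = TRUE)
  y <- y[ord]; s <- score[ord]
  grp <- cumsum(!duplicated(s))
  tp <- unlist(lapply(split(y, grp), sum))
  np <- unlist(lapply(split(y, grp), length))
  n1 <- sum(y); n0 <- length(y) - n1
  tibble(fpr = c(0, cumsum(np - tp) / max(n0, 1L)),
         tpr = c(0, cumsum(tp) / max(n1, 1L)))
}

metric_cols <- c("accuracy", "ci_halfwidth", "sensitivity", "specificity",
                 "f_score", "auc")

#' Unweighted mean row over fold results
#'
#' Arithmetic mean of each metric across folds (each fold counts equally
#' regardless of its size); `NA` metrics are dropped per column. A
#' size-weighted variant is available via `weights = "size"`.
#'
#' @param fold_results a tibble of fold results (rows = folds).
#' @param weights `"equal"` (default) or `"size"` (weight by fold `n`).
#' @return a one-row tibble with `fold_label = "Mean"`.
#' @export
aggregate_mean_row <- function(fold_results, weights = c("equal", "size")) {
  weights <- match.arg(weights)
  stopifnot(nrow(fold_results) >= 1L)
  present <- intersect(metric_cols, names(fold_results))
  wmean <- function(x) {
    w <- if (weights == "size") fold_results$n else rep(1, nrow(fold_results))
    ok <- !is.na(x)
    if (!any(ok)) return(NA_real_)
    sum(x[ok] * w[ok]) / sum(w[ok])
  }
  out <- tibble(fold_label = if (weights == "equal") "Mean" else "WeightedMean")
  for (mc in present) out[[mc]] <- wmean(fold_results[[mc]])
  if ("n" %in% names(fold_results)) out$n <- mean(fold_results$n)
  out
}

#' Train and evaluate across a split plan
#'
#' For each fold, re-initializes and trains a classifier on the training
#' indices and scores the held-out test indices. By default the classifier is
#' the row-convolution network ([build_model()] + [train()]) with a per-fold
#' seed derived deterministically from `tconf$seed`; any function
#' `f(train_conns, train_labels, test_conns)` returning a B x 2 probability
#' matrix can be substituted via `classifier` (used e.g. for harness oracles).
#'
#' @param cohort cohort tibble (`diagnosis` supplies the labels).
#' @param connectomes list of connectome matrices aligned with `cohort` rows.
#' @param plan a `split_plan`.
#' @param mconf a [model_config()]; ignored when `classifier` is given.
#' @param tconf a [train_config()].
#' @param classifier optional custom classifier function.
#' @return an `eval_report`: list with `folds` (fold-result tibble),
#'   `mean_row`, `weighted_mean_row`, `pooled` (out-of-fold predictions) and
#'   `pooled_roc`.
#' @export
cross_validate <- function(cohort, connectomes, plan,
                           mconf = model_config(), tconf = train_config(),
                           classifier = NULL) {
  stopifnot(inherits(plan, "split_plan"),
            nrow(cohort) == length(connectomes))
  y <- encode_labels(cohort$diagnosis)
  nfold <- nrow(plan)
  fold_seeds <- with_seed(tconf$seed, sample.int(1e6, nfold))
  folds <- vector("list", nfold)
  pooled <- vector("list", nfold)
  for (f in seq_len(nfold)) {
    tr <- plan$train[[f]]; te <- plan$test[[f]]
    stopifnot(length(intersect(tr, te)) == 0L)
    if (is.null(classifier)) {
      tc_f <- tconf
      tc_f$seed <- fold_seeds[f]
      mdl <- build_model(mconf, seed = fold_seeds[f])
      mdl <- train(mdl, connectomes[tr], y[tr], tc_f)
      probs <- predict_proba(mdl, connectomes[te])
    } else {
      probs <- classifier(connectomes[tr], y[tr], connectomes[te])
    }
    folds[[f]] <- compute_metrics(y[te], probs, fold_label = plan$fold_label[f])
    pooled[[f]] <- tibble(fold_label = plan$fold_label[f],
                          y_true = y[te], p_asd = probs[, 2L])
  }
  new_eval_report(bind_rows(folds), bind_rows(pooled),
                  scheme = attr(plan, "scheme"), seed = tconf$seed)
}

# assemble an eval_report from per-fold metrics and pooled predictions
new_eval_report <- function(fold_tbl, pooled_tbl, scheme, seed) {
  structure(list(
    folds = fold_tbl,
    mean_row = aggregate_mean_row(fold_tbl, "equal"),
    weighted_mean_row = aggregate_mean_row(fold_tbl, "size"),
    pooled = pooled_tbl,
    pooled_roc = roc_points(pooled_tbl$y_true, pooled_tbl$p_asd),
    scheme = scheme,
    seed = seed
  ), class = "eval_report")
}

#' Constant majority-class classifier (evaluation-harness oracle)
#'
#' Predicts the training-set majority class (probability 1) for every test
#' subject. Its per-fold accuracy is exactly the fraction of the test fold
#' belonging to the training majority class, which makes it a closed-form
#' oracle for the cross-validation harness.
#'
#' @param train_conns,train_labels,test_conns classifier interface arguments.
#' @return a B x 2 probability matrix.
#' @export
majority_classifier <- function(train_conns, train_labels, test_conns) {
  y <- encode_labels(train_labels)
  maj <- as.integer(mean(y) >= 0.5)
  probs <- matrix(0, length(test_conns), 2L)
  probs[, maj + 1L] <- 1
  colnames(probs) <- class_names(2L)
  probs
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> scheme:", x$scheme, "-", nrow(x$folds), "folds\n")
  print(as.data.frame(bind_rows(x$folds, x$mean_row)[, c("fold_label", "n",
                                                         metric_cols)]),
        digits = 4, row.names = FALSE)
  invisible(x)
}

#' @describeIn cross_validate per-fold metric tibble of an `eval_report`.
#' @param x an `eval_report`.
#' @param ... unused.
#' @export
tidy.eval_report <- function(x, ...) {
  x$folds
}

#' @describeIn cross_validate one-row summary (unweighted mean metrics).
#' @export
glance.eval_report <- function(x, ...) {
  out <- x$mean_row
  out$fold_label <- NULL
  out$scheme <- x$scheme
  out$n_folds <- nrow(x$folds)
  out
}
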