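#' Persist and reload an evaluation report
#'
#' `write_report()` writes two files: a human-readable CSV at `path` with one
#' row per fold plus the unweighted `Mean` row (columns fold label, test
#' size, accuracy, CI half-width, sensitivity, specificity, F-score, AUC and
#' the confusion counts) and a full-precision JSON sidecar at
#' `paste0(path, ".json")` carrying every field of the report.
#' `read_report()` restores the report from the JSON sidecar bit-identically
#' (numbers are serialized at full precision).
#'
#' @param report an `eval_report` from [cross_validate()].
#' @param path output CSV path; the JSON sidecar is derived from it.
#' @return `path` invisibly (write); an `eval_report` (read).
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  tbl <- bind_rows(report$folds, report$mean_row)
  cols <- intersect(c("fold_label", "n", "accuracy", "ci_halfwidth",
                      "sensitivity", "specificity", "f_score", "auc",
                      "tn", "fp", "fn", "tp"), names(tbl))
  utils::write.csv(as.data.frame(tbl[, cols]), path, row.names = FALSE,
                   quote = FALSE)
  payload <- list(
    scheme = report$scheme,
    seed = report$seed,
    folds = report$folds,
    mean_row = report$mean_row,
    weighted_mean_row = report$weighted_mean_row,
    pooled = report$pooled,
    pooled_roc = report$pooled_roc,
    confusion_total = unname(c(sum(report$folds$tn), sum(report$folds$fp),
                               sum(report$folds$fn), sum(report$folds$tp)))
  )
  # I(17) significant digits round-trips doubles bit-identically
  jsonlite::write_json(payload, paste0(path, ".json"), digits = I(17),
                       auto_unbox = TRUE, dataframe = "columns", na = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jpath <- if (endsWith(path, ".json")) path else paste0(path, ".json")
  payload <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  fix_tbl <- function(x) {
    tb <- as_tibble(as.data.frame(x, stringsAsFactors = FALSE))
    tb
  }
  folds <- fix_tbl(payload$folds)
  class(folds) <- c("fold_result", class(folds))
  structure(list(
    folds = folds,
    mean_row = fix_tbl(payload$mean_row),
    weighted_mean_row = fix_tbl(payload$weighted_mean_row),
    pooled = fix_tbl(payload$pooled),
    pooled_roc = fix_tbl(payload$pooled_roc),
    scheme = payload$scheme,
    seed = payload$seed
  ), class = "eval_report")
}
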