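# shared fixtures: tiny cohorts, file writers, and a brute-force correlation
# oracle kept independent of the package implementation

write_tmp_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".txt", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

write_tmp_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

tiny_cohort <- function(n = 6L, seed = 1L) {
  set.seed(seed)
  tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    site_id = rep_len(c("A", "B"), n),
    diagnosis = factor(rep_len(c("ASD", "TC"), n), levels = c("TC", "ASD")),
    mean_fd = round(runif(n, 0, 0.3), 3)
  )
}

# two-pass covariance / standard-deviation Pearson correlation, element by
# element -- the independent oracle for pearson_connectome()
brute_force_cor <- function(ts) {
  R <- ncol(ts)
  out <- matrix(NA_real_, R, R)
  for (i in seq_len(R)) {
    for (j in seq_len(R)) {
      xi <- ts[, i]; xj <- ts[, j]
      cov_ij <- sum((xi - mean(xi)) * (xj - mean(xj))) / (length(xi) - 1)
      sdi <- sqrt(sum((xi - mean(xi))^2) / (length(xi) - 1))
      sdj <- sqrt(sum((xj - mean(xj))^2) / (length(xj) - 1))
      out[i, j] <- cov_ij / (sdi * sdj)
    }
  }
  out
}

random_symmetric_input <- function(R, seed) {
  set.seed(seed)
  x <- matrix(rnorm(R * R), R, R)
  x <- (x + t(x)) / 2
  diag(x) <- 1
  x
}

# pre-softmax class score via the public surface only (log prob differences
# recover logit differences; used where logits themselves are not needed)
tiny_model <- function(R = 6L, K = c(1L, 2L), F = 3L, seed = 1L) {
  build_model(model_config(n_rois = R, branch_lengths = K, n_filters = F),
              seed = seed)
}
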