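#' Pearson functional-connectivity matrix from ROI time series
#'
#' Computes the R x R matrix of Pearson correlation coefficients between ROI
#' time series — the functional connectome that serves as the classifier
#' input. The result is exactly symmetric with a unit diagonal; no Fisher
#' z-transform is applied.
#'
#' @param ts a T x R numeric matrix (rows = timepoints, columns = ROIs),
#'   T >= 2.
#' @param impute_zero if `TRUE`, ROIs with zero temporal variance get zero
#'   off-diagonal correlations (with a warning) instead of raising an error.
#' @param roi_labels optional character vector of length R; defaults to
#'   `C1 ... CR`.
#' @return an R x R correlation matrix with ROI labels as dimnames.
#' @export
pearson_connectome <- function(ts, impute_zero = FALSE, roi_labels = NULL) {
  stopifnot(is.matrix(ts), is.numeric(ts))
  if (nrow(ts) < 2L) {
    abort("need at least 2 timepoints to correlate", class = "conncnn_data_error")
  }
  if (anyNA(ts)) {
    abort("time series contains missing values", class = "conncnn_data_error")
  }
  R <- ncol(ts)
  sds <- apply(ts, 2L, stats::sd)
  flat <- which(sds == 0)
  if (length(flat) > 0L && !impute_zero) {
    abort(paste0("zero-variance ROI(s): ",
                 paste(paste0("C", flat), collapse = ", "),
                 "; rerun with impute_zero = TRUE to zero them out"),
          class = "conncnn_data_error")
  }
  conn <- suppressWarnings(stats::cor(ts))
  if (length(flat) > 0L) {
    warn(paste0("imputing zero correlation for ", length(flat),
                " zero-variance ROI(s)"))
    conn[flat, ] <- 0
    conn[, flat] <- 0
  }
  conn <- (conn + t(conn)) / 2          # remove last-bit asymmetry
  diag(conn) <- 1
  labels <- roi_labels %||% paste0("C", seq_len(R))
  dimnames(conn) <- list(labels, labels)
  conn
}

#' Vectorize the strict upper triangle of a connectome
#'
#' Flattens the strictly-upper-triangular entries in row-major order — the
#' feature vector consumed by the classical baselines. Length is
#' `R * (R - 1) / 2` (76,636 for R = 392).
#'
#' @param conn an R x R connectome matrix.
#' @return a numeric vector of length `R * (R - 1) / 2`.
#' @export
vectorize_upper_triangle <- function(conn) {
  stopifnot(is.matrix(conn), nrow(conn) == ncol(conn))
  # row-major upper triangle == column-major lower triangle of the transpose
  t(conn)[lower.tri(conn)]
}

#' Rebuild a symmetric unit-diagonal connectome from its upper triangle
#'
#' Inverse of [vectorize_upper_triangle()] under the connectome invariants
#' (symmetry, diagonal of ones).
#'
#' @param v a vector of length `R * (R - 1) / 2`.
#' @param roi_labels optional labels for the reconstructed matrix.
#' @return an R x R symmetric matrix with unit diagonal.
#' @export
connectome_from_vector <- function(v, roi_labels = NULL) {
  R <- (1 + sqrt(1 + 8 * length(v))) / 2
  if (R != round(R)) {
    abort("vector length is not R*(R-1)/2 for any integer R",
          class = "conncnn_data_error")
  }
  R <- as.integer(R)
  m <- matrix(0, R, R)
  tm <- t(m)
  tm[lower.tri(tm)] <- v
  m <- t(tm)
  m <- m + t(m)
  diag(m) <- 1
  labels <- roi_labels %||% paste0("C", seq_len(R))
  dimnames(m) <- list(labels, labels)
  m
}

#' Validate connectome invariants
#'
#' Checks symmetry (within `tol`), entries in `[-1, 1]` and a unit diagonal.
#' Used defensively by the model and simulation code.
#'
#' @param conn matrix to check.
#' @param tol symmetry tolerance.
#' @return `TRUE` invisibly, or an error describing the violated invariant.
#' @keywords internal
#' @export
validate_connectome <- function(conn, tol = 1e-12) {
  stopifnot(is.matrix(conn))
  if (nrow(conn) != ncol(conn)) {
    abort("connectome is not square", class = "conncnn_data_error")
  }
  if (max(abs(conn - t(conn))) > tol) {
    abort("connectome is not symmetric", class = "conncnn_data_error")
  }
  if (any(conn < -1 - tol) || any(conn > 1 + tol)) {
    abort("connectome has entries outside [-1, 1]", class = "conncnn_data_error")
  }
  if (any(diag(conn) != 1)) {
    abort("connectome diagonal is not identically 1", class = "conncnn_data_error")
  }
  invisible(TRUE)
}
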