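#' Read an ROI time-series matrix from whitespace-delimited text
#'
#' Reads the plain-text matrix convention used by pipeline ROI extractions
#' (`.1D`-style): one row per timepoint, one column per ROI, whitespace
#' separated. Lines whose first non-blank character is `#` are treated as
#' comments/headers and skipped.
#'
#' @param path path to a text file.
#' @return a numeric T x R matrix (T timepoints, R ROIs).
#' @export
read_roi_timeseries <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("time-series file not found: ", path),
          class = "conncnn_format_error")
  }
  lines <- readLines(path, warn = FALSE)
  blank <- !nzchar(trimws(lines))
  comment <- startsWith(trimws(lines), "#")
  keep <- which(!blank & !comment)
  if (length(keep) == 0L) {
    abort("time-series file contains no data rows", class = "conncnn_format_error")
  }
  rows <- strsplit(trimws(lines[keep]), "[[:space:]]+")
  widths <- lengths(rows)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1L])[1L]
    abort(paste0("ragged time-series file: line ", keep[bad], " has ",
                 widths[bad], " fields, expected ", widths[1L]),
          class = "conncnn_format_error")
  }
  vals <- suppressWarnings(as.numeric(unlist(rows)))
  if (anyNA(vals)) {
    abort("non-numeric value in time-series file", class = "conncnn_format_error")
  }
  ts <- matrix(vals, nrow = length(rows), ncol = widths[1L], byrow = TRUE)
  if (nrow(ts) < 2L) {
    abort("time-series has fewer than 2 timepoints; correlation is undefined",
          class = "conncnn_data_error")
  }
  ts
}

#' Write / read a connectome as a plain-text matrix
#'
#' The on-disk format is R rows of R whitespace-delimited reals, optionally
#' preceded by a `#`-prefixed header line carrying ROI labels.
#'
#' @param conn an R x R connectome matrix.
#' @param path output path.
#' @return `path` (write) or the connectome matrix with ROI labels restored
#'   as dimnames (read).
#' @export
write_connectome <- function(conn, path) {
  stopifnot(is.matrix(conn), nrow(conn) == ncol(conn))
  con <- file(path, "w")
  on.exit(close(con))
  labels <- colnames(conn) %||% paste0("C", seq_len(ncol(conn)))
  writeLines(paste0("# ", paste(labels, collapse = " ")), con)
  utils::write.table(format(conn, digits = 17, trim = TRUE, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_connectome
#' @export
read_connectome <- function(path) {
  lines <- readLines(path, warn = FALSE)
  header <- startsWith(trimws(lines), "#")
  labels <- NULL
  if (any(header)) {
    labels <- strsplit(trimws(sub("^\\s*#\\s*", "", lines[which(header)[1L]])),
                       "[[:space:]]+")[[1L]]
  }
  rows <- strsplit(trimws(lines[!header & nzchar(trimws(lines))]), "[[:space:]]+")
  m <- matrix(as.numeric(unlist(rows)), nrow = length(rows), byrow = TRUE)
  if (nrow(m) != ncol(m)) {
    abort("connectome file is not square", class = "conncnn_format_error")
  }
  if (!is.null(labels) && length(labels) == ncol(m)) {
    dimnames(m) <- list(labels, labels)
  }
  m
}
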