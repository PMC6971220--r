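#' Read a phenotype table into a cohort tibble
#'
#' Parses a phenotype CSV (one row per subject) into the cohort tibble used
#' throughout the package: `subject_id`, `site_id`, `diagnosis` (factor with
#' levels `TC`, `ASD`), `mean_fd` (mean framewise displacement, mm), and
#' optional `age`, `sex` and `timeseries_ref` columns. Column names follow the
#' public multi-site release convention (`SUB_ID`, `SITE_ID`, `DX_GROUP`,
#' `FUNC_MEAN_FD`) but can be remapped via `columns`. Diagnosis codes default
#' to the convention `1 = ASD`, `2 = TC`; pass `dx_map` to override.
#'
#' Rows with a missing subject id or an unparseable diagnosis are dropped with
#' a warning; the number of rejected rows is recorded in the returned tibble's
#' `"provenance"` attribute.
#'
#' @param path path to a CSV file.
#' @param columns named character vector mapping canonical field names
#'   (`subject_id`, `site_id`, `diagnosis`, `mean_fd`, and optionally `age`,
#'   `sex`, `timeseries_ref`) to column names in the file.
#' @param dx_map named character vector mapping diagnosis codes (as they
#'   appear in the file, coerced to character) to `"ASD"` / `"TC"`.
#' @return a cohort tibble with a `"provenance"` attribute.
#' @export
read_phenotype <- function(path,
                           columns = c(subject_id = "SUB_ID",
                                       site_id = "SITE_ID",
                                       diagnosis = "DX_GROUP",
                                       mean_fd = "FUNC_MEAN_FD"),
                           dx_map = c("1" = "ASD", "2" = "TC")) {
  if (!file.exists(path)) {
    abort(paste0("phenotype file not found: ", path), class = "conncnn_format_error")
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0L) {
    abort("phenotype file is empty", class = "conncnn_format_error")
  }
  required <- c("subject_id", "site_id", "diagnosis", "mean_fd")
  defaults <- c(subject_id = "SUB_ID", site_id = "SITE_ID",
                diagnosis = "DX_GROUP", mean_fd = "FUNC_MEAN_FD",
                age = "AGE_AT_SCAN", sex = "SEX", timeseries_ref = "FILE_ID")
  colmap <- defaults
  colmap[names(columns)] <- columns
  for (field in required) {
    if (!colmap[[field]] %in% names(raw)) {
      abort(paste0("phenotype file lacks required column '", colmap[[field]],
                   "' (", field, ")"),
            class = "conncnn_format_error")
    }
  }

  dx_raw <- as.character(raw[[colmap[["diagnosis"]]]])
  dx <- unname(dx_map[dx_raw])
  # codes already spelled out pass through
  dx[dx_raw %in% c("ASD", "TC")] <- dx_raw[dx_raw %in% c("ASD", "TC")]
  id <- as.character(raw[[colmap[["subject_id"]]]])

  bad <- is.na(dx) | !dx %in% c("ASD", "TC") | is.na(id) | id == ""
  n_rejected <- sum(bad)
  if (n_rejected > 0L) {
    warn(paste0(n_rejected, " phenotype row(s) rejected (missing id or ",
                "unparseable diagnosis)"))
  }

  keep <- !bad
  out <- tibble(
    subject_id = id[keep],
    site_id = as.character(raw[[colmap[["site_id"]]]])[keep],
    diagnosis = factor(dx[keep], levels = c("TC", "ASD")),
    mean_fd = as.numeric(raw[[colmap[["mean_fd"]]]])[keep]
  )
  if (colmap[["age"]] %in% names(raw)) {
    out$age <- as.numeric(raw[[colmap[["age"]]]])[keep]
  }
  if (colmap[["sex"]] %in% names(raw)) {
    out$sex <- as.character(raw[[colmap[["sex"]]]])[keep]
  }
  if (colmap[["timeseries_ref"]] %in% names(raw)) {
    out$timeseries_ref <- as.character(raw[[colmap[["timeseries_ref"]]]])[keep]
  }
  if (anyDuplicated(out$subject_id)) {
    abort("duplicate subject_id in phenotype file", class = "conncnn_format_error")
  }
  attr(out, "provenance") <- list(source = path, n_rejected = n_rejected)
  out
}

#' Write a cohort tibble back to a phenotype CSV
#'
#' Inverse of [read_phenotype()] for the canonical column names, so a cohort
#' round-trips through disk unchanged on `(subject_id, site_id, diagnosis,
#' mean_fd)`.
#'
#' @param cohort a cohort tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_phenotype <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  out <- data.frame(
    SUB_ID = cohort$subject_id,
    SITE_ID = cohort$site_id,
    DX_GROUP = ifelse(as.character(cohort$diagnosis) == "ASD", 1L, 2L),
    FUNC_MEAN_FD = cohort$mean_fd
  )
  if ("age" %in% names(cohort)) out$AGE_AT_SCAN <- cohort$age
  if ("sex" %in% names(cohort)) out$SEX <- cohort$sex
  if ("timeseries_ref" %in% names(cohort)) out$FILE_ID <- cohort$timeseries_ref
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Remove high-motion subjects by mean framewise displacement
#'
#' Drops subjects whose mean framewise displacement exceeds `threshold`
#' (strictly greater than; subjects exactly at the threshold are kept). This
#' is the standard motion quality filter applied before classification.
#'
#' @param cohort a cohort tibble with a `mean_fd` column.
#' @param threshold motion cutoff in mm; default 0.2.
#' @return the filtered cohort, input order preserved; the number of removed
#'   subjects is reported via `inform()` and stored in the `"n_removed"`
#'   attribute.
#' @export
filter_by_mean_fd <- function(cohort, threshold = 0.2) {
  stopifnot(is.data.frame(cohort), threshold > 0)
  keep <- !(cohort$mean_fd > threshold)
  keep[is.na(keep)] <- FALSE
  out <- cohort[keep, , drop = FALSE]
  n_removed <- nrow(cohort) - nrow(out)
  inform(paste0("filter_by_mean_fd: removed ", n_removed, " of ",
                nrow(cohort), " subjects (mean FD > ", threshold, " mm)"))
  attr(out, "n_removed") <- n_removed
  attr(out, "provenance") <- attr(cohort, "provenance")
  out
}
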