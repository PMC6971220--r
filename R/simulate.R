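#' Configuration for synthetic multi-site cohorts
#'
#' The generator emulates the structure the classifier assumes: two
#' diagnostic groups whose connectomes differ on the edges among a planted
#' set of ROIs, with additive per-site offsets and subject-level noise.
#' Effects are planted in Fisher-z space and mapped through `tanh`, which
#' guarantees valid correlations and gives closed-form expected group
#' differences. Defaults define the scaled study conditions used throughout
#' the test suite: 64 ROIs, 8 planted ROIs, 100 subjects per group across 4
#' sites.
#'
#' @param n_per_group subjects per diagnostic group; default 100.
#' @param n_rois number of ROIs R; default 64.
#' @param n_timepoints timepoints T for the time-series mode; default 160.
#' @param planted_rois ROI indices carrying the group effect; default `1:8`.
#' @param delta group shift (z-space) on edges within `planted_rois`;
#'   default 1.0.
#' @param base_mu baseline edge mean in z-space; default 0.2.
#' @param noise_sd edge noise SD in z-space; default 0.3.
#' @param n_sites number of acquisition sites; default 4.
#' @param site_sd SD of per-site additive z-space offsets; default 0.1.
#' @param ts_base_loading shared-signal loading of planted ROIs in control
#'   subjects (time-series mode); default 0.3.
#' @param ts_delta extra loading in ASD subjects (time-series mode);
#'   default 0.6.
#' @param seed integer seed; the entire cohort is reproducible from it.
#' @return a `sim_config` object.
#' @export
sim_config <- function(n_per_group = 100L, n_rois = 64L, n_timepoints = 160L,
                       planted_rois = 1:8, delta = 1.0, base_mu = 0.2,
                       noise_sd = 0.3, n_sites = 4L, site_sd = 0.1,
                       ts_base_loading = 0.3, ts_delta = 0.6, seed = 1L) {
  planted_rois <- as.integer(planted_rois)
  stopifnot(n_per_group >= 1L, n_rois >= 2L, n_timepoints >= 2L,
            noise_sd > 0, n_sites >= 1L, site_sd >= 0,
            all(planted_rois >= 1L), all(planted_rois <= n_rois),
            !anyDuplicated(planted_rois))
  structure(list(n_per_group = as.integer(n_per_group),
                 n_rois = as.integer(n_rois),
                 n_timepoints = as.integer(n_timepoints),
                 planted_rois = planted_rois, delta = delta,
                 base_mu = base_mu, noise_sd = noise_sd,
                 n_sites = as.integer(n_sites), site_sd = site_sd,
                 ts_base_loading = ts_base_loading, ts_delta = ts_delta,
                 seed = as.integer(seed)),
            class = "sim_config")
}

sim_cohort_frame <- function(cfg) {
  n <- 2L * cfg$n_per_group
  tibble(
    subject_id = sprintf("S%04d", seq_len(n)),
    site_id = paste0("SITE", rep_len(seq_len(cfg$n_sites), n)),
    diagnosis = factor(rep(c("ASD", "TC"), each = cfg$n_per_group),
                       levels = c("TC", "ASD")),
    mean_fd = stats::runif(n, 0, 0.3)
  )
}

#' Simulate a multi-site cohort of connectomes
#'
#' For each subject, off-diagonal edge values are drawn in Fisher-z space as
#' `z_ij ~ N(base_mu + site_offset + planted * delta, noise_sd^2)` for
#' `i < j`, where `planted` is 1 iff the subject is ASD and both i and j are
#' planted ROIs; the connectome is `tanh(z)` symmetrized with unit diagonal.
#' Site offsets are drawn once per site from `N(0, site_sd^2)`; subjects are
#' assigned to sites round-robin. `mean_fd` is Uniform(0, 0.3) so the motion
#' filter is exercisable. Bit-reproducible from `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return list with `cohort` (tibble) and `connectomes` (named list of R x R
#'   matrices); the expected planted-edge group difference
#'   `tanh(base_mu + delta) - tanh(base_mu)` is attached as attribute
#'   `"expected_effect"` (site/noise averaging shrinks the realized value
#'   slightly below this).
#' @export
simulate_connectomes <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  R <- cfg$n_rois
  planted <- cfg$planted_rois
  with_seed(cfg$seed, {
    cohort <- sim_cohort_frame(cfg)
    site_offsets <- stats::rnorm(cfg$n_sites, 0, cfg$site_sd)
    names(site_offsets) <- paste0("SITE", seq_len(cfg$n_sites))
    n_edges <- R * (R - 1L) / 2L
    ut <- upper.tri(matrix(0, R, R))
    planted_edge <- matrix(FALSE, R, R)
    planted_edge[planted, planted] <- TRUE
    planted_vec <- planted_edge[ut]
    conns <- vector("list", nrow(cohort))
    for (i in seq_len(nrow(cohort))) {
      mu <- cfg$base_mu + site_offsets[[cohort$site_id[i]]] +
        (cohort$diagnosis[i] == "ASD") * cfg$delta * planted_vec
      z <- stats::rnorm(n_edges, mu, cfg$noise_sd)
      m <- matrix(0, R, R)
      m[ut] <- tanh(z)
      m <- m + t(m)
      diag(m) <- 1
      dimnames(m) <- list(paste0("C", seq_len(R)), paste0("C", seq_len(R)))
      conns[[i]] <- m
    }
    names(conns) <- cohort$subject_id
    out <- list(cohort = cohort, connectomes = conns)
    attr(out, "expected_effect") <-
      tanh(cfg$base_mu + cfg$delta) - tanh(cfg$base_mu)
    attr(out, "config") <- cfg
    out
  })
}

#' Simulate ROI time series with a planted shared signal
#'
#' Latent-factor model: every subject has a shared standard-normal signal on
#' which the planted ROIs load — loading `ts_base_loading` for controls and
#' `ts_base_loading + ts_delta` for ASD subjects — plus independent
#' unit-variance noise in every ROI. Correlating the output with
#' [pearson_connectome()] therefore shows elevated planted-edge correlation
#' in the ASD group (approximately `c^2 / (c^2 + 1)` at loading `c`).
#'
#' @param cfg a [sim_config()].
#' @return list with `cohort` and `timeseries` (named list of T x R
#'   matrices).
#' @export
simulate_timeseries <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  R <- cfg$n_rois; T <- cfg$n_timepoints
  with_seed(cfg$seed, {
    cohort <- sim_cohort_frame(cfg)
    ts_list <- vector("list", nrow(cohort))
    for (i in seq_len(nrow(cohort))) {
      c0 <- cfg$ts_base_loading +
        (cohort$diagnosis[i] == "ASD") * cfg$ts_delta
      loading <- numeric(R)
      loading[cfg$planted_rois] <- c0
      u <- stats::rnorm(T)
      ts_list[[i]] <- u %o% loading + matrix(stats::rnorm(T * R), T, R)
    }
    names(ts_list) <- cohort$subject_id
    out <- list(cohort = cohort, timeseries = ts_list)
    attr(out, "config") <- cfg
    out
  })
}

#' Write a simulated cohort to disk in the package's file formats
#'
#' Produces a phenotype CSV plus one text matrix per subject (connectome or
#' time series), so the full file-based pipeline runs on simulated data
#' unchanged.
#'
#' @param sim output of [simulate_connectomes()] or [simulate_timeseries()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- sim$cohort
  mats <- sim$connectomes %||% sim$timeseries
  kind <- if (is.null(sim$connectomes)) "timeseries" else "connectome"
  cohort$timeseries_ref <- paste0(cohort$subject_id, "_", kind, ".txt")
  write_phenotype(cohort, file.path(dir, "phenotype.csv"))
  for (i in seq_len(nrow(cohort))) {
    p <- file.path(dir, cohort$timeseries_ref[i])
    if (kind == "connectome") {
      write_connectome(mats[[i]], p)
    } else {
      utils::write.table(format(mats[[i]], digits = 17, trim = TRUE),
                         p, row.names = FALSE, col.names = FALSE, quote = FALSE)
    }
  }
  invisible(dir)
}
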