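#' Simulate and fit one synthetic subject
#'
#' Runs the single-subject arm of the pipeline: build the subject's cortical
#' sheet from its (typically jittered, see [jitter_config()]) scenario
#' config, simulate `n_scans` BOLD scans under the design's stimulus, detrend
#' each scan, average, and fit pRF models to every node.
#'
#' @param config a [scenario_config()] (one subject's constants and seed).
#' @param design a [prf_design()] for the stimulus/HRF/candidate bank.
#' @param n_scans repeated scans to simulate and average.
#' @param detrend_order polynomial detrend order per scan.
#' @param refine polish fits by local search (slower; off by default for
#'   cohort work where band-level statistics are the target).
#' @param target_snr optional SNR override passed to [simulate_bold()].
#' @return the subject's node table: the cortical sheet columns plus fitted
#'   `x`, `y`, `sigma`, `amplitude`, `variance_explained`, `eccentricity`,
#'   `polar_angle`.
#' @export
fit_synthetic_subject <- function(config, design, n_scans = 4,
                                  detrend_order = 2, refine = FALSE,
                                  target_snr = NULL) {
  sheet <- build_sheet(config)
  scans <- simulate_bold(sheet, design$seq, design$hrf, n_scans = n_scans,
                         config = config, target_snr = target_snr)
  for (s in seq_len(n_scans))
    scans[, , s] <- detrend_ts(scans[, , s], order = detrend_order)
  y <- average_scans(scans)
  fit <- prf_fit(y, design = design, refine = refine)
  est <- fit$estimates
  nodes <- cbind(sheet,
                 est[, c("x", "y", "sigma", "amplitude",
                         "variance_explained", "eccentricity",
                         "polar_angle")])
  class(nodes) <- c("cortical_sheet", "data.frame")
  attr(nodes, "config") <- config
  nodes
}

#' Hemisphere-averaged eccentricity-band profiles for one subject
#'
#' Computes, per visual field map, the three band statistics (surface area,
#' mean variance explained, mean sigma) separately per hemisphere, averages
#' them between hemispheres, and derives the surface-area percent
#' distribution from the hemisphere-averaged areas (normalized over all bands
#' in `bands`). Hemisphere averaging precedes any group analysis.
#'
#' @param nodes a subject node table from [fit_synthetic_subject()] (or any
#'   data.frame with `hemisphere`, `map_group`, `area`, `sigma`,
#'   `eccentricity`, `variance_explained`).
#' @param bands an [make_ecc_bands()] object.
#' @param ve_threshold variance-explained threshold for area and sigma.
#' @return tidy data.frame: `map`, `band_center`, `statistic`
#'   (area_mm2 / area_percent / mean_ve / mean_sigma), `value`.
#' @export
subject_band_profiles <- function(nodes, bands = make_ecc_bands(),
                                  ve_threshold = 0.04) {
  hemis <- unique(nodes$hemisphere)
  one_stat <- function(statistic) {
    per_h <- lapply(hemis, function(h)
      band_profile(nodes[nodes$hemisphere == h, ], bands, statistic,
                   ve_threshold))
    out <- per_h[[1]][, c("map", "band_center", "statistic")]
    vals <- sapply(per_h, function(p) p$value)
    out$value <- rowMeans(as.matrix(vals), na.rm = TRUE)
    out$value[is.nan(out$value)] <- NA_real_
    out
  }
  area <- one_stat("area_mm2")
  pct <- area
  totals <- tapply(area$value, area$map, sum)
  pct$value <- ifelse(totals[pct$map] > 0,
                      100 * pct$value / as.numeric(totals[pct$map]),
                      NA_real_)
  pct$statistic <- "area_percent"
  out <- rbind(area, pct, one_stat("mean_ve"), one_stat("mean_sigma"))
  rownames(out) <- NULL
  out
}

# subjects x bands matrix for one (map, statistic) from a list of profiles
profiles_matrix <- function(profiles, map, statistic, centers = NULL) {
  rows <- lapply(profiles, function(p) {
    sel <- p[p$map == map & p$statistic == statistic, ]
    sel <- sel[order(sel$band_center), ]
    if (!is.null(centers)) sel <- sel[sel$band_center %in% centers, ]
    stats::setNames(sel$value, sel$band_center)
  })
  do.call(rbind, rows)
}

#' Pipeline configuration
#'
#' All knobs of [run_pipeline()] in one serializable list: stimulus geometry,
#' HRF, candidate bank, preprocessing, thresholds, cohort composition, and the
#' master seed. A pipeline run is reproducible from this object alone.
#'
#' @param scenarios named integer vector: subjects per scenario (names are
#'   [scenario_config()] scenario names). The first two scenarios are
#'   compared in the group statistics.
#' @param grid_resolution,field_radius,bar_width,frame_duration stimulus
#'   parameters, see [make_bar_sequence()].
#' @param hrf an [hrf_params()] object.
#' @param n_xy,sigmas candidate bank parameters, see [prf_grid()].
#' @param n_scans,detrend_order,refine per-subject processing options.
#' @param ve_threshold variance-explained threshold for area/sigma profiles.
#' @param n_u,n_v lattice size of each subject's V1 (see [scenario_config()]).
#' @param seed master RNG seed; per-subject seeds are drawn from it.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(scenarios = c(young = 5, aging = 4),
                            grid_resolution = 61, field_radius = 11,
                            bar_width = field_radius / 4, frame_duration = 2,
                            hrf = hrf_params(), n_xy = 17,
                            sigmas = exp(seq(log(0.25), log(field_radius),
                                             length.out = 10)),
                            n_scans = 4, detrend_order = 2, refine = FALSE,
                            ve_threshold = 0.04, n_u = 20, n_v = 6,
                            seed = 1L) {
  stopifnot(length(scenarios) >= 1, !is.null(names(scenarios)))
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full simulation-and-analysis pipeline
#'
#' End-to-end run on synthetic cohorts: generate the bar stimulus, build the
#' pRF design, simulate and fit every subject of every scenario
#' (jittered per subject), compute hemisphere-averaged band profiles, and —
#' when at least two scenarios are present — compare the first two groups:
#' central and peripheral MANOVAs per map for surface-area percent, variance
#' explained and pRF size, plus a one-way ANOVA on total map area.
#' Deterministic given the config (including its seed).
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, profiles, group statistics
#'   and a provenance log are written as CSV/text files.
#' @return a list of class `pipeline_result`: `profiles` (tidy subject-level
#'   band profiles), `totals` (per-subject total map areas), `stats` (tidy
#'   group-comparison table, `NULL` for single-scenario runs), `subjects`
#'   (per-subject node tables), `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seq <- make_bar_sequence(config$grid_resolution, config$field_radius,
                           config$bar_width, config$frame_duration)
  design <- prf_design(seq, config$hrf,
                       prf_grid(config$field_radius, config$n_xy,
                                config$sigmas))
  bands <- make_ecc_bands()

  set.seed(config$seed)
  n_total <- sum(config$scenarios)
  subject_seeds <- sample.int(.Machine$integer.max, n_total)

  subjects <- list(); profiles <- list(); totals <- list()
  meta <- data.frame(subject = character(), group = character())
  si <- 0L
  for (g in names(config$scenarios)) {
    base <- scenario_config(g, field_radius = config$field_radius,
                            n_u = config$n_u, n_v = config$n_v)
    for (j in seq_len(config$scenarios[[g]])) {
      si <- si + 1L
      id <- sprintf("%s_%02d", g, j)
      cfg <- jitter_config(base, subject_seeds[si])
      nodes <- fit_synthetic_subject(cfg, design, n_scans = config$n_scans,
                                     detrend_order = config$detrend_order,
                                     refine = config$refine)
      subjects[[id]] <- nodes
      prof <- subject_band_profiles(nodes, bands, config$ve_threshold)
      prof$subject <- id; prof$group <- g
      profiles[[id]] <- prof
      ta <- total_map_area_by_hemi(nodes, config$ve_threshold)
      totals[[id]] <- data.frame(subject = id, group = g,
                                 map = names(ta), area_mm2 = as.numeric(ta))
      meta <- rbind(meta, data.frame(subject = id, group = g))
    }
  }
  profiles_df <- do.call(rbind, profiles)
  rownames(profiles_df) <- NULL
  totals_df <- do.call(rbind, totals)
  rownames(totals_df) <- NULL

  stats_df <- NULL
  if (length(config$scenarios) >= 2)
    stats_df <- group_stats_table(profiles, totals_df, meta,
                                  groups = names(config$scenarios)[1:2])

  res <- structure(list(profiles = profiles_df, totals = totals_df,
                        stats = stats_df, subjects = subjects,
                        config = config),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

# per-subject total map area, averaged between hemispheres
total_map_area_by_hemi <- function(nodes, ve_threshold = 0.04) {
  per_h <- lapply(split(nodes, nodes$hemisphere), total_map_area,
                  ve_threshold = ve_threshold)
  maps <- unique(nodes$map_group)
  out <- rowMeans(sapply(per_h, function(x) x[maps]))
  stats::setNames(out, maps)
}

# tidy table of the standard group comparisons between two scenario groups
group_stats_table <- function(profiles, totals_df, meta, groups) {
  rows <- list()
  ids1 <- meta$subject[meta$group == groups[1]]
  ids2 <- meta$subject[meta$group == groups[2]]
  maps <- unique(profiles[[1]]$map)
  subsets <- list(central = central_bands(), peripheral = peripheral_bands())
  for (m in maps) {
    for (stat in c("area_percent", "mean_ve", "mean_sigma")) {
      for (s in names(subsets)) {
        g1 <- profiles_matrix(profiles[ids1], m, stat, subsets[[s]])
        g2 <- profiles_matrix(profiles[ids2], m, stat, subsets[[s]])
        cmp <- tryCatch(manova_bands(g1, g2, map = m),
                        error = function(e) NULL)
        if (is.null(cmp)) next
        rows[[length(rows) + 1]] <- data.frame(
          map = m, statistic = stat, subset = s, test = "manova",
          stat = cmp$statistic, df1 = cmp$df[1], df2 = cmp$df[2],
          p = cmp$p_value)
      }
    }
    a1 <- totals_df$area_mm2[totals_df$map == m & totals_df$group == groups[1]]
    a2 <- totals_df$area_mm2[totals_df$map == m & totals_df$group == groups[2]]
    cmp <- anova_total_area(list(a1, a2), map = m)
    rows[[length(rows) + 1]] <- data.frame(
      map = m, statistic = "total_area", subset = "all", test = "anova",
      stat = cmp$statistic, df1 = cmp$df[1], df2 = cmp$df[2], p = cmp$p_value)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$profiles, file.path(out_dir, "profiles.csv"),
                   row.names = FALSE)
  utils::write.csv(res$totals, file.path(out_dir, "total_areas.csv"),
                   row.names = FALSE)
  if (!is.null(res$stats))
    utils::write.csv(res$stats, file.path(out_dir, "group_stats.csv"),
                     row.names = FALSE)
  cfg <- res$config
  prov <- c(sprintf("prfmap %s", as.character(utils::packageVersion("prfmap"))),
            sprintf("run at %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
            sprintf("seed %d", cfg$seed),
            sprintf("scenarios: %s",
                    paste(names(cfg$scenarios), cfg$scenarios, sep = "=",
                          collapse = ", ")),
            utils::capture.output(utils::str(cfg, give.attr = FALSE)))
  writeLines(prov, file.path(out_dir, "provenance.txt"))
  invisible(res)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pRF mapping pipeline result\n")
  cat(sprintf("  %d subjects (%s), %d profile rows\n",
              length(x$subjects),
              paste(names(x$config$scenarios), x$config$scenarios, sep = "=",
                    collapse = ", "),
              nrow(x$profiles)))
  if (!is.null(x$stats)) {
    cat("  group comparisons:\n")
    print(x$stats, digits = 3)
  }
  invisible(x)
}
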