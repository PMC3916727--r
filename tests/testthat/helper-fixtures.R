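# Shared fixtures, built once per test run. Reduced sizes: a coarser aperture
# grid and a small candidate bank keep every fit cheap while preserving the
# geometry (field radius, timing) of the full stimulus.

fix_seq <- make_bar_sequence(grid_resolution = 41)
fix_grid <- prf_grid(field_radius = 11, n_xy = 11,
                     sigmas = c(0.5, 1, 2, 4, 8))
fix_design <- prf_design(fix_seq, hrf_params(), fix_grid)

# naive single-voxel grid search: independent oracle for the vectorised
# fitter. Shares its degenerate-candidate rule: numerically constant
# predictions (pRFs wholly outside the field) score 0.
oracle_fit <- function(y, design) {
  sds <- apply(design$pred, 2, stats::sd)
  best_ve <- -1; best <- NULL
  for (i in seq_len(nrow(design$grid))) {
    pred <- design$pred[, i]
    ve <- if (sds[i] < max(sds) * 1e-5) 0
          else as.numeric(variance_explained(pred, y))
    if (ve > best_ve + 1e-15) {
      best_ve <- ve
      best <- design$grid[i, ]
    }
  }
  list(x = best$x, y = best$y, sigma = best$sigma, ve = best_ve)
}

# candidate indices with real stimulus-driven predictions (identifiable truths)
live_candidates <- function(design) {
  sds <- apply(design$pred, 2, stats::sd)
  which(sds > max(sds) * 1e-5)
}

# truth-level node table: treats ground truth as if it were a perfect fit
truth_nodes <- function(sheet, ve = 1) {
  data.frame(map_group = sheet$map_group, hemisphere = sheet$hemisphere,
             area = sheet$area, eccentricity = sheet$truth_ecc,
             sigma = sheet$truth_sigma, variance_explained = ve)
}
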