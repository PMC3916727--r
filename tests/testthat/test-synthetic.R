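test_that("young sheet over-represents the fovea in cortical area", {
  sheet <- build_sheet(scenario_config("young"))
  v1 <- sheet[sheet$map_group == "V1", ]
  frac_fovea <- sum(v1$area[v1$truth_ecc < 3]) / sum(v1$area)
  frac_periph <- sum(v1$area[v1$truth_ecc > 7 & v1$truth_ecc < 10]) /
    sum(v1$area)
  expect_gt(frac_fovea, frac_periph)
  # eccentricity increases monotonically along u in every unperturbed map
  for (m in unique(sheet$map)) {
    sub <- sheet[sheet$map == m & sheet$hemisphere == "L", ]
    expect_true(all(diff(sub$truth_ecc[order(sub$u)]) >= -1e-12))
  }
  # hemifield coverage: V1/hV4 span the full contralateral hemifield
  for (m in c("V1", "hV4")) {
    l <- sheet[sheet$map == m & sheet$hemisphere == "L", ]
    expect_lt(min(l$truth_angle), -60)
    expect_gt(max(l$truth_angle), 60)
    expect_true(all(l$truth_x >= 0))   # left hemisphere: right hemifield
  }
  # per-map areas are positive and sum to the map total
  expect_true(all(sheet$area > 0))
})

test_that("sheet generation is reproducible from its config", {
  cfg <- scenario_config("young", seed = 123)
  expect_identical(build_sheet(cfg), build_sheet(cfg))
  j1 <- jitter_config(cfg, 77)
  j2 <- jitter_config(cfg, 77)
  expect_identical(j1, j2)
  expect_false(identical(jitter_config(cfg, 78)$a, j1$a))
})

test_that("aging preset shrinks foveal area and enlarges foveal pRFs", {
  young <- build_sheet(scenario_config("young"))
  aging <- build_sheet(scenario_config("aging"))
  yv1 <- young[young$map_group == "V1", ]
  av1 <- aging[aging$map_group == "V1", ]
  expect_lt(sum(av1$area[av1$truth_ecc < 3]), sum(yv1$area[yv1$truth_ecc < 3]))
  expect_equal(sum(av1$area[av1$truth_ecc > 3]), sum(yv1$area[yv1$truth_ecc > 3]))
  # ground-truth foveal sigma near the 2-degree anchor
  expect_equal(mean(av1$truth_sigma[av1$truth_ecc < 1]), 2, tolerance = 0.15)
  expect_gt(mean(av1$truth_sigma[av1$truth_ecc < 3]) /
              mean(yv1$truth_sigma[yv1$truth_ecc < 3]), 2)
})

test_that("AD scrambling disorders eccentricity but not polar angle", {
  young <- build_sheet(scenario_config("young"))
  scr <- build_sheet(scenario_config("ad_scrambled"))
  y <- young[young$map == "V1" & young$hemisphere == "L", ]
  s <- scr[scr$map == "V1" & scr$hemisphere == "L", ]
  expect_lt(stats::cor(s$u, s$truth_ecc, method = "spearman"),
            stats::cor(y$u, y$truth_ecc, method = "spearman") - 0.3)
  expect_equal(stats::cor(s$v, s$truth_angle, method = "spearman"),
               stats::cor(y$v, y$truth_angle, method = "spearman"))
  expect_lt(unique(s$truth_amplitude), unique(y$truth_amplitude))
})

test_that("AD truncation caps ground-truth eccentricity at the cutoff", {
  cfg <- scenario_config("ad_truncated", peripheral_cutoff = 5)
  sheet <- build_sheet(cfg)
  expect_equal(max(sheet$truth_ecc), 5)
  expect_error(scenario_config("ad_truncated", peripheral_cutoff = 20),
               "cutoff")
})

test_that("noiseless simulation round-trips through fitting for on-grid truths", {
  cfg <- scenario_config("young",
                         noise = list(sd = 0, ar1 = 0, drift_amplitude = 0),
                         n_u = 4, n_v = 2)
  sheet <- build_sheet(cfg)
  sheet <- sheet[sheet$hemisphere == "L" & sheet$map == "V1", ]
  class(sheet) <- c("cortical_sheet", "data.frame")
  attr(sheet, "config") <- cfg
  # snap truths onto the candidate bank
  set.seed(2)
  idx <- sample(nrow(fix_design$grid), nrow(sheet))
  sheet$truth_x <- fix_design$grid$x[idx]
  sheet$truth_y <- fix_design$grid$y[idx]
  sheet$truth_sigma <- fix_design$grid$sigma[idx]
  scans <- simulate_bold(sheet, fix_seq, hrf_params(), n_scans = 1,
                         config = cfg)
  fit <- prf_fit(detrend_ts(scans[, , 1], 0), design = fix_design,
                 refine = FALSE)
  expect_equal(fit$estimates$x, sheet$truth_x)
  expect_equal(fit$estimates$y, sheet$truth_y)
  expect_equal(fit$estimates$sigma, sheet$truth_sigma)
  expect_true(all(fit$estimates$variance_explained > 1 - 1e-6))
})

test_that("unresponsive nodes fit like the noise-only null", {
  cfg <- scenario_config("young", n_u = 6, n_v = 3)
  sheet <- build_sheet(cfg)
  sheet <- sheet[sheet$map_group == "V1" & sheet$hemisphere == "L", ]
  sheet$truth_amplitude <- 0
  class(sheet) <- c("cortical_sheet", "data.frame")
  attr(sheet, "config") <- cfg
  scans <- simulate_bold(sheet, fix_seq, hrf_params(), n_scans = 1,
                         config = cfg, seed = 31)
  fit <- prf_fit(detrend_ts(scans[, , 1], 2), design = fix_design,
                 refine = FALSE)
  expect_gte(mean(fit$estimates$variance_explained < 0.2), 0.95)
})

test_that("doubling the number of scans halves the averaged noise variance", {
  cfg <- scenario_config("young", n_u = 4, n_v = 2)
  sheet <- build_sheet(cfg)
  sheet <- sheet[sheet$hemisphere == "L" & sheet$map == "V1", ][1:4, ]
  sheet$truth_amplitude <- 0          # isolate the noise process
  class(sheet) <- c("cortical_sheet", "data.frame")
  attr(sheet, "config") <- cfg
  set.seed(41)
  ratio <- replicate(40, {
    s4 <- simulate_bold(sheet, fix_seq, n_scans = 4, config = cfg,
                        seed = sample.int(1e6, 1))
    s8 <- simulate_bold(sheet, fix_seq, n_scans = 8, config = cfg,
                        seed = sample.int(1e6, 1))
    v4 <- mean(apply(detrend_ts(average_scans(s4), 2), 2, stats::var))
    v8 <- mean(apply(detrend_ts(average_scans(s8), 2), 2, stats::var))
    v4 / v8
  })
  expect_equal(mean(ratio), 2, tolerance = 0.2)
})

test_that("simulated BOLD is reproducible and carries drift plus AR noise", {
  cfg <- scenario_config("young", n_u = 4, n_v = 2)
  sheet <- build_sheet(cfg)
  sheet <- sheet[1:5, ]
  class(sheet) <- c("cortical_sheet", "data.frame")
  a <- simulate_bold(sheet, fix_seq, n_scans = 2, config = cfg, seed = 9)
  b <- simulate_bold(sheet, fix_seq, n_scans = 2, config = cfg, seed = 9)
  expect_identical(a, b)
  expect_equal(dim(a), c(96L, 5L, 2L))
})
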