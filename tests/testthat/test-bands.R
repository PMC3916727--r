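test_that("eccentricity bands tile the analysis range", {
  b <- make_ecc_bands(0, 10, 1)
  expect_equal(nrow(b), 10)
  expect_equal(b$center, seq(0.5, 9.5, by = 1))
  expect_equal(b$lo, 0:9)
  expect_equal(make_ecc_bands(0, 1, 1)$center, 0.5)
  expect_error(make_ecc_bands(0, 10, 3), "divide")
  expect_error(make_ecc_bands(5, 2), "exceed")
})

test_that("band surface area sums thresholded node areas half-openly", {
  nodes <- data.frame(map = "V1", eccentricity = seq(0.5, 9.5, 1),
                      variance_explained = 1, area = 1)
  prof <- band_surface_area(nodes)
  expect_equal(prof$value, rep(1, 10))
  expect_equal(prof$n_nodes, rep(1L, 10))
  # sub-threshold nodes contribute nowhere
  nodes$variance_explained[3] <- 0.039
  expect_equal(band_surface_area(nodes, ve_threshold = 0.04)$value[3], 0)
  # boundary values belong to the upper band; >= 10 deg fall out entirely
  edge <- data.frame(map = "V1", eccentricity = c(1, 10),
                     variance_explained = 1, area = 1)
  p <- band_surface_area(edge)
  expect_equal(p$value[p$band_center == 1.5], 1)
  expect_equal(p$value[p$band_center == 0.5], 0)
  expect_equal(sum(p$value), 1)
  expect_error(band_surface_area(nodes[, -4]), "area")
})

test_that("band statistics equal a naive per-node loop on random data", {
  set.seed(8)
  n <- 1000
  nodes <- data.frame(
    map = sample(c("V1", "V2", "V3", "hV4"), n, replace = TRUE),
    eccentricity = stats::runif(n, 0, 12),
    variance_explained = stats::runif(n),
    sigma = stats::runif(n, 0.2, 5),
    area = stats::runif(n, 0.5, 2))
  bands <- make_ecc_bands()
  for (stat in c("area_mm2", "mean_ve", "mean_sigma")) {
    prof <- band_profile(nodes, bands, stat)
    thr <- if (stat == "mean_ve") -Inf else 0.04
    for (r in sample(nrow(prof), 40)) {
      sel <- nodes$map == prof$map[r] &
        nodes$eccentricity >= bands$lo[match(prof$band_center[r], bands$center)] &
        nodes$eccentricity < bands$hi[match(prof$band_center[r], bands$center)] &
        nodes$variance_explained >= thr
      expected <- switch(stat,
                         area_mm2 = sum(nodes$area[sel]),
                         mean_ve = mean(nodes$variance_explained[sel]),
                         mean_sigma = mean(nodes$sigma[sel]))
      if (stat == "area_mm2" && !any(sel)) expected <- 0
      expect_equal(prof$value[r], expected)
      expect_equal(prof$n_nodes[r], sum(sel))
    }
  }
  # permutation invariance in node order
  perm <- sample(n)
  expect_equal(band_profile(nodes[perm, ], bands, "mean_sigma")$value,
               band_profile(nodes, bands, "mean_sigma")$value)
  # total area equals the naive thresholded sum
  tot <- total_map_area(nodes)
  expect_equal(as.numeric(tot["V2"]),
               sum(nodes$area[nodes$map == "V2" &
                                nodes$variance_explained >= 0.04]))
})

test_that("percent distribution normalizes to 100 over its band set", {
  nodes <- data.frame(map = "V1", eccentricity = seq(0.5, 9.5, 1),
                      variance_explained = 1, area = 2)
  prof <- band_surface_area(nodes)
  pct <- percent_distribution(prof)
  expect_equal(pct$value, rep(10, 10))
  expect_equal(sum(pct$value), 100, tolerance = 1e-6)
  # single loaded band
  one <- nodes; one$area <- c(5, rep(0, 9))
  p1 <- percent_distribution(band_surface_area(one))
  expect_equal(p1$value[p1$band_center == 0.5], 100)
  expect_equal(sum(p1$value), 100)
  # restricted reporting keeps the full-map denominator
  pr <- percent_distribution(prof, include = seq(1.5, 9.5, 1))
  expect_equal(nrow(pr), 9)
  expect_equal(sum(pr$value), 90)
  # zero-area map flagged
  empty <- nodes; empty$variance_explained <- 0
  pe <- percent_distribution(band_surface_area(empty))
  expect_true(all(is.na(pe$value)))
  expect_equal(attr(pe, "empty_maps"), "V1")
})

test_that("mean VE is unthresholded and empty bands are flagged missing", {
  nodes <- data.frame(map = "V1",
                      eccentricity = c(0.2, 0.4, 2.5),
                      variance_explained = c(0.5, 0.5, 0.01),
                      sigma = 2, area = 1)
  ve <- band_mean_ve(nodes)
  expect_equal(ve$value[ve$band_center == 0.5], 0.5)
  expect_equal(ve$value[ve$band_center == 2.5], 0.01)   # no threshold
  expect_true(is.na(ve$value[ve$band_center == 5.5]))
  expect_equal(ve$n_nodes[ve$band_center == 5.5], 0L)
  sg <- band_mean_sigma(nodes)
  expect_equal(sg$value[sg$band_center == 0.5], 2)
  expect_true(is.na(sg$value[sg$band_center == 2.5]))   # thresholded out
})

test_that("ground-truth profiles show the expected retinotopic structure", {
  young <- build_sheet(scenario_config("young"))
  nodes <- truth_nodes(young)
  sg <- band_mean_sigma(nodes)
  v1 <- sg[sg$map == "V1" & !is.na(sg$value), ]
  expect_true(all(diff(v1$value[order(v1$band_center)]) > 0))
  # truncated sheet piles its area into the low bands only
  trunc <- truth_nodes(build_sheet(scenario_config("ad_truncated")))
  ta <- band_surface_area(trunc)
  expect_true(all(ta$value[ta$band_center > 6] == 0))
  expect_gt(sum(ta$value[ta$band_center < 6]), 0)
  # every map holds thresholded area in the central bands
  sa <- band_surface_area(nodes)
  expect_true(all(sa$value[sa$band_center < 3] > 0))
})

test_that("hemisphere averaging commutes with band extraction", {
  set.seed(12)
  base <- data.frame(map_group = "V1",
                     eccentricity = rep(seq(0.25, 9.75, by = 0.5), 2),
                     variance_explained = 1,
                     sigma = stats::runif(40, 1, 3),
                     area = stats::runif(40, 0.5, 2))
  nodes <- rbind(cbind(base, hemisphere = "L"),
                 cbind(base[sample(40), ], hemisphere = "R"))
  prof <- subject_band_profiles(nodes)
  pooled <- band_mean_sigma(nodes)   # equal node counts per hemisphere
  got <- prof$value[prof$statistic == "mean_sigma"]
  expect_equal(got, pooled$value, tolerance = 1e-9)
})
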