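test_that("forward prediction respects stimulus geometry", {
  s <- fix_seq
  # pRF far outside the field never responds
  expect_equal(predict_timecourse(100, 0, 0.5, s), rep(0, s$n_frames))
  # a near-flat Gaussian responds in proportion to the convolved on-count
  big <- predict_timecourse(0, 0, 50, s)
  kernel <- hrf_kernel(hrf_params(), dt = s$frame_duration)
  counts <- stats::convolve(c(rowSums(s$masks), numeric(length(kernel))),
                            rev(kernel), type = "open")[1:s$n_frames]
  expect_gt(stats::cor(big, counts), 0.9999)
  expect_error(predict_timecourse(0, 0, -1, s), "sigma")
})

test_that("prediction is symmetric under point reflection of the stimulus", {
  s <- fix_seq
  # reflect every frame through fixation by permuting grid cells
  refl <- s
  perm <- order(round(-s$x, 9), round(-s$y, 9))
  orig <- order(round(s$x, 9), round(s$y, 9))
  map <- integer(length(perm)); map[orig] <- perm
  refl$masks <- s$masks[, map]
  for (par in list(c(3, 2, 1), c(-4, 0.5, 2.5), c(0, -7, 0.7))) {
    expect_equal(predict_timecourse(par[1], par[2], par[3], s),
                 predict_timecourse(-par[1], -par[2], par[3], refl),
                 tolerance = 1e-10)
  }
})

test_that("variance explained behaves as a scale-free goodness of fit", {
  set.seed(11)
  pred <- predict_timecourse(2, 1, 1.5, fix_seq)
  expect_equal(variance_explained(pred, 3 * pred), 1)
  expect_equal(variance_explained(pred, 3 * pred + 10), 1)
  # orthogonal data
  pc <- pred - mean(pred)
  orth <- stats::rnorm(length(pred))
  orth <- orth - mean(orth)
  orth <- orth - pc * sum(orth * pc) / sum(pc^2)
  expect_equal(variance_explained(pred, orth), 0, tolerance = 1e-12)
  # equal signal and noise variance gives about one half
  ve <- replicate(100, {
    n <- stats::rnorm(length(pred), sd = stats::sd(pred))
    as.numeric(variance_explained(pred, pred + n))
  })
  expect_equal(mean(ve), 0.5, tolerance = 0.1)
  # zero-variance data are flagged
  out <- variance_explained(pred, rep(2, length(pred)))
  expect_equal(as.numeric(out), 0)
  expect_true(attr(out, "no_signal"))
})

test_that("variance explained and coherence interconvert", {
  expect_equal(ve_to_coherence(0.04), 0.20)
  expect_equal(ve_to_coherence(1), 1)
  expect_equal(ve_to_coherence(0.0225), 0.15)
  v <- seq(0, 1, by = 0.05)
  expect_equal(coherence_to_ve(ve_to_coherence(v)), v)
  expect_error(ve_to_coherence(1.2), "0, 1")
  expect_error(coherence_to_ve(-0.1), "0, 1")
})

test_that("eccentricity and polar angle derive from the pRF center", {
  expect_equal(ecc_angle(3, 4), data.frame(eccentricity = 5,
                                           polar_angle = 53.13),
               tolerance = 1e-4)
  expect_equal(ecc_angle(0, 0)$polar_angle, 0)
  expect_equal(ecc_angle(-1, 0)$polar_angle, 180)
  expect_equal(ecc_angle(0, -2)$polar_angle, -90)
})

test_that("grid fitter matches a brute-force candidate enumeration", {
  set.seed(21)
  expect_lte(nrow(fix_design$grid), 11 * 11 * 5)
  for (i in 1:5) {
    truth <- fix_design$grid[sample(nrow(fix_design$grid), 1), ]
    y <- fix_design$pred[, as.integer(rownames(truth))] +
      stats::rnorm(fix_seq$n_frames, sd = 2)
    y <- detrend_ts(y, 1)
    fit <- prf_fit(y, design = fix_design, refine = FALSE)
    oracle <- oracle_fit(y, fix_design)
    expect_equal(fit$estimates$x, oracle$x)
    expect_equal(fit$estimates$y, oracle$y)
    expect_equal(fit$estimates$sigma, oracle$sigma)
    expect_equal(fit$estimates$variance_explained, oracle$ve,
                 tolerance = 1e-10)
  }
})

test_that("on-grid truths are recovered exactly from noiseless data", {
  set.seed(3)
  idx <- sample(live_candidates(fix_design), 10)
  fit <- prf_fit(fix_design$pred[, idx], design = fix_design, refine = FALSE)
  expect_equal(fit$estimates$x, fix_design$grid$x[idx])
  expect_equal(fit$estimates$y, fix_design$grid$y[idx])
  expect_equal(fit$estimates$sigma, fix_design$grid$sigma[idx])
  expect_true(all(abs(fit$estimates$variance_explained - 1) < 1e-6))
})

test_that("fitting is deterministic and flags signal-free voxels", {
  set.seed(5)
  y <- detrend_ts(stats::rnorm(96), 1)
  f1 <- prf_fit(y, design = fix_design, refine = TRUE)
  f2 <- prf_fit(y, design = fix_design, refine = TRUE)
  expect_identical(f1$estimates, f2$estimates)
  z <- prf_fit(rep(0, 96), design = fix_design, refine = FALSE)
  expect_true(z$estimates$no_signal)
  expect_equal(z$estimates$variance_explained, 0)
  expect_true(is.na(z$estimates$x))
  expect_error(prf_fit(rep(0, 50), design = fix_design), "length")
})

test_that("white noise rarely exceeds the conventional threshold by much", {
  set.seed(99)
  low <- replicate(100, {
    y <- detrend_ts(stats::rnorm(96), 1)
    prf_fit(y, design = fix_design, refine = FALSE)$estimates$variance_explained
  })
  expect_gte(mean(low < 0.2), 0.95)
})

test_that("local refinement recovers off-grid parameters from noisy data", {
  set.seed(13)
  ok <- replicate(20, {
    truth <- c(x = stats::runif(1, -6, 6), y = stats::runif(1, -6, 6),
               sigma = stats::runif(1, 0.8, 3))
    sig <- predict_timecourse(truth[1], truth[2], truth[3], fix_seq)
    y <- sig / stats::sd(sig) + stats::rnorm(96, sd = 0.2)  # SNR 5
    est <- prf_fit(detrend_ts(y, 1), design = fix_design,
                   refine = TRUE)$estimates
    abs(est$x - truth[1]) < 0.5 && abs(est$y - truth[2]) < 0.5 &&
      abs(est$sigma - truth[3]) / truth[3] < 0.25
  })
  expect_gte(mean(ok), 0.9)
})

test_that("prf_fit methods are mutually consistent", {
  set.seed(17)
  sig <- predict_timecourse(1, -2, 1.2, fix_seq)
  y <- detrend_ts(2 * sig / stats::sd(sig) + stats::rnorm(96, sd = 0.3), 1)
  fit <- prf_fit(y, design = fix_design, refine = TRUE)
  expect_equal(drop(fit$data) - fitted(fit), residuals(fit))
  expect_equal(colnames(coef(fit)), c("x", "y", "sigma", "amplitude"))
  expect_equal(dim(as.matrix(predict(fit, data.frame(x = 0, y = 0,
                                                     sigma = 1)))),
               c(96L, 1L))
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_equal(dim(sims[[1]]), c(96L, 1L))
  s <- summary(fit)
  expect_s3_class(s, "summary.prf_fit")
  expect_output(print(fit), "pRF model fit")
})
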