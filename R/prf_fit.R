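#' Candidate bank for the pRF grid search
#'
#' Builds the bank of candidate 2D Gaussian pRFs evaluated exhaustively during
#' fitting: centers on a regular lattice spanning the field of view and
#' spreads log-spaced over roughly the range resolvable with a bar stimulus.
#' Candidates are ordered ascending in sigma, then y, then x; the fitter
#' breaks exact ties by this scan order, making fits deterministic.
#'
#' @param field_radius field of view radius, degrees.
#' @param n_xy lattice points per axis for the center (default 25 x 25).
#' @param sigmas candidate spreads in degrees; default 16 log-spaced values
#'   from 0.25 to `field_radius`.
#' @return a data.frame of candidates with columns `x`, `y`, `sigma`.
#' @export
prf_grid <- function(field_radius = 11, n_xy = 25,
                     sigmas = exp(seq(log(0.25), log(field_radius),
                                      length.out = 16))) {
  stopifnot(field_radius > 0, n_xy >= 2, all(sigmas > 0))
  pos <- seq(-field_radius, field_radius, length.out = n_xy)
  xy <- expand.grid(x = pos, y = pos, KEEP.OUT.ATTRS = FALSE)
  out <- do.call(rbind, lapply(sort(sigmas), function(s)
    cbind(xy, sigma = s)))
  rownames(out) <- NULL
  out
}

#' Precomputed pRF design: candidate predictions for a stimulus
#'
#' Evaluates the forward model once for every candidate in the bank —
#' Gaussian-aperture overlap per frame, then causal HRF convolution — so that
#' many voxels can be fitted against the same stimulus cheaply. Build one
#' design per (stimulus, HRF, candidate bank) and pass it to [prf_fit()].
#'
#' @param seq an [make_bar_sequence()] aperture sequence.
#' @param hrf an [hrf_params()] object.
#' @param grid a candidate bank from [prf_grid()].
#' @return an object of class `prf_design`.
#' @export
prf_design <- function(seq, hrf = hrf_params(),
                       grid = prf_grid(seq$field_radius)) {
  stopifnot(inherits(seq, "aperture_sequence"), inherits(hrf, "hrf_params"))
  kernel <- hrf_kernel(hrf, dt = seq$frame_duration)
  cmat <- conv_matrix(kernel, seq$n_frames)
  sig <- unique(grid$sigma)
  xy <- grid[grid$sigma == sig[1], c("x", "y")]
  d2 <- outer(seq$x, xy$x, "-")^2 + outer(seq$y, xy$y, "-")^2
  pred <- matrix(0, nrow = seq$n_frames, ncol = nrow(grid))
  for (i in seq_along(sig)) {
    w <- exp(-d2 / (2 * sig[i]^2))
    cols <- which(grid$sigma == sig[i])
    pred[, cols] <- cmat %*% (seq$masks %*% w)
  }
  structure(list(pred = pred, grid = grid, seq = seq, hrf = hrf,
                 kernel = kernel, cmat = cmat),
            class = "prf_design")
}

# lower-triangular Toeplitz operator for causal FIR convolution
conv_matrix <- function(kernel, n) {
  m <- matrix(0, n, n)
  for (j in seq_along(kernel)) {
    idx <- seq_len(n - j + 1)
    m[cbind(idx + j - 1, idx)] <- kernel[j]
  }
  m
}

#' Predicted BOLD time course of a 2D Gaussian pRF
#'
#' Forward model for one pRF: the per-frame overlap of a unit-height
#' isotropic Gaussian centered at (x, y) with spread sigma against each
#' aperture frame, convolved causally with the HRF sampled at the frame
#' duration and truncated to the sequence length.
#'
#' @param x,y pRF center, degrees.
#' @param sigma pRF spread, degrees (> 0).
#' @param seq an [make_bar_sequence()] aperture sequence.
#' @param hrf an [hrf_params()] object.
#' @return numeric predicted series, one value per frame.
#' @export
predict_timecourse <- function(x, y, sigma, seq, hrf = hrf_params()) {
  stopifnot(inherits(seq, "aperture_sequence"))
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  w <- exp(-((seq$x - x)^2 + (seq$y - y)^2) / (2 * sigma^2))
  convolve_hrf(as.numeric(seq$masks %*% w),
               hrf_kernel(hrf, dt = seq$frame_duration))
}

#' Fit 2D Gaussian pRF models to BOLD time series
#'
#' The central model-fitting routine: for each voxel, every candidate pRF in
#' the bank is scored by the variance its HRF-convolved prediction explains
#' after a nonnegative-amplitude + intercept least-squares fit; the best
#' candidate is optionally polished by a derivative-free local search over
#' (x, y, log sigma). Fits are deterministic given the inputs: exact score
#' ties resolve to the first candidate in scan order (ascending sigma, then
#' y, then x).
#'
#' Input series should be detrended (see [detrend_ts()]) and, when repeated
#' scans exist, averaged (see [average_scans()]). A voxel whose series has no
#' variance is returned with `variance_explained = 0`, `no_signal = TRUE`,
#' and `NA` parameters rather than an error.
#'
#' Candidates whose predictions are numerically constant — pRFs wholly
#' outside the stimulated field — score 0 rather than letting floating-point
#' residue correlate with noise.
#'
#' @param y numeric vector (one voxel) or frames x voxels matrix.
#' @param seq an [make_bar_sequence()] aperture sequence; ignored when
#'   `design` is supplied.
#' @param hrf an [hrf_params()] object; ignored when `design` is supplied.
#' @param grid candidate bank from [prf_grid()]; ignored when `design` is
#'   supplied.
#' @param refine logical: polish the grid optimum by Nelder-Mead local search
#'   (recommended whenever the true center can fall between lattice points).
#' @param design a prebuilt [prf_design()]; supply this when fitting many
#'   datasets against one stimulus.
#' @return an object of class `prf_fit`. Component `estimates` is a
#'   data.frame with one row per voxel: `x`, `y`, `sigma`, `amplitude`,
#'   `intercept`, `variance_explained`, `eccentricity`, `polar_angle`,
#'   `no_signal`.
#' @examples
#' seq <- make_bar_sequence(grid_resolution = 51)
#' des <- prf_design(seq, grid = prf_grid(11, n_xy = 9, sigmas = c(0.5, 1, 2)))
#' y <- predict_timecourse(2, 1, 1, seq)
#' fit <- prf_fit(y, design = des, refine = FALSE)
#' coef(fit)
#' @export
prf_fit <- function(y, seq = NULL, hrf = hrf_params(), grid = NULL,
                    refine = TRUE, design = NULL) {
  if (is.null(design)) {
    if (is.null(seq)) stop("supply either `seq` or a prebuilt `design`",
                           call. = FALSE)
    if (is.null(grid)) grid <- prf_grid(seq$field_radius)
    design <- prf_design(seq, hrf, grid)
  }
  ym <- as.matrix(y)
  if (nrow(ym) != nrow(design$pred))
    stop("time series length (", nrow(ym), ") does not match the stimulus (",
         nrow(design$pred), " frames)", call. = FALSE)
  nvox <- ncol(ym)

  pc <- sweep(design$pred, 2, colMeans(design$pred))
  ssp <- colSums(pc^2)
  yc <- sweep(ym, 2, colMeans(ym))
  ssy <- colSums(yc^2)
  no_signal <- ssy < 1e-12

  cp <- crossprod(pc, yc)                     # candidates x voxels
  cp[cp < 0] <- 0                             # nonnegative amplitude
  ve <- cp^2 / (pmax(ssp, 1e-300) * rep(pmax(ssy, 1e-300), each = nrow(cp)))
  # degenerate candidates (numerically constant predictions, e.g. centers
  # wholly outside the stimulated field) score 0 rather than amplify noise
  ve[ssp < max(ssp) * 1e-10, ] <- 0
  best <- max.col(t(ve), ties.method = "first")

  g <- design$grid[best, , drop = FALSE]
  est <- data.frame(x = g$x, y = g$y, sigma = g$sigma)
  idx <- cbind(best, seq_len(nvox))
  est$amplitude <- cp[idx] / pmax(ssp[best], 1e-300)
  est$variance_explained <- pmin(ve[idx], 1)

  if (refine) {
    for (v in which(!no_signal)) {
      ref <- refine_prf(est$x[v], est$y[v], est$sigma[v], yc[, v], design)
      if (ref$ve >= est$variance_explained[v]) {
        est$x[v] <- ref$x; est$y[v] <- ref$y; est$sigma[v] <- ref$sigma
        est$amplitude[v] <- ref$amplitude
        est$variance_explained[v] <- min(ref$ve, 1)
      }
    }
  }

  est$intercept <- colMeans(ym) - est$amplitude * vapply(seq_len(nvox),
    function(v) mean(model_pred(est$x[v], est$y[v], est$sigma[v], design)),
    numeric(1))
  est[no_signal, c("x", "y", "sigma", "amplitude", "intercept")] <- NA_real_
  est$variance_explained[no_signal] <- 0
  est$no_signal <- no_signal
  pa <- ecc_angle(est$x, est$y)
  est$eccentricity <- pa$eccentricity
  est$polar_angle <- pa$polar_angle
  est <- est[, c("x", "y", "sigma", "amplitude", "intercept",
                 "variance_explained", "eccentricity", "polar_angle",
                 "no_signal")]

  structure(list(estimates = est, data = ym, design = design,
                 refine = refine, call = match.call()),
            class = "prf_fit")
}

# unconvolved-model prediction given a design (internal)
model_pred <- function(x, y, sigma, design) {
  s <- design$seq
  w <- exp(-((s$x - x)^2 + (s$y - y)^2) / (2 * sigma^2))
  as.numeric(design$cmat %*% (s$masks %*% w))
}

# local polish of the grid optimum; yc must be mean-centered
refine_prf <- function(x0, y0, s0, yc, design) {
  r <- design$seq$field_radius
  ssy <- sum(yc^2)
  obj <- function(p) {
    sig <- exp(p[3])
    if (sig < 0.05 || sig > 2 * r || abs(p[1]) > r + 2 || abs(p[2]) > r + 2)
      return(0)
    pred <- model_pred(p[1], p[2], sig, design)
    pcv <- pred - mean(pred)
    ssp <- sum(pcv^2)
    if (ssp < 1e-12) return(0)
    -max(sum(pcv * yc), 0)^2 / (ssp * ssy)
  }
  o <- stats::optim(c(x0, y0, log(s0)), obj, method = "Nelder-Mead",
                    control = list(maxit = 150, reltol = 1e-7))
  sig <- exp(o$par[3])
  pred <- model_pred(o$par[1], o$par[2], sig, design)
  pcv <- pred - mean(pred)
  amp <- max(sum(pcv * yc), 0) / max(sum(pcv^2), 1e-300)
  list(x = o$par[1], y = o$par[2], sigma = sig, amplitude = amp,
       ve = -o$value)
}
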