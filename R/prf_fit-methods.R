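#' @export
print.prf_fit <- function(x, ...) {
  est <- x$estimates
  cat("pRF model fit\n")
  cat(sprintf("  %d voxel(s), %d frames, candidate bank of %d pRFs%s\n",
              nrow(est), nrow(x$data), nrow(x$design$grid),
              if (x$refine) ", local refinement" else ""))
  cat(sprintf("  variance explained: median %.3f, %.0f%% of voxels >= 0.04\n",
              stats::median(est$variance_explained),
              100 * mean(est$variance_explained >= 0.04)))
  invisible(x)
}

#' @export
coef.prf_fit <- function(object, ...) {
  as.matrix(object$estimates[, c("x", "y", "sigma", "amplitude")])
}

#' @export
fitted.prf_fit <- function(object, ...) {
  est <- object$estimates
  out <- matrix(NA_real_, nrow(object$data), nrow(est))
  for (v in which(!est$no_signal)) {
    out[, v] <- est$amplitude[v] *
      model_pred(est$x[v], est$y[v], est$sigma[v], object$design) +
      est$intercept[v]
  }
  drop(out)
}

#' @export
residuals.prf_fit <- function(object, ...) {
  drop(object$data - as.matrix(fitted(object)))
}

#' Predict BOLD time courses from a pRF fit
#'
#' Without `newparams`, returns the fitted time courses. With `newparams` (a
#' data.frame or matrix with columns `x`, `y`, `sigma`), returns unit-amplitude
#' predictions for those pRFs under the fit's stimulus and HRF.
#'
#' @param object a [prf_fit()] object.
#' @param newparams optional pRF parameters to predict for.
#' @param ... unused.
#' @export
predict.prf_fit <- function(object, newparams = NULL, ...) {
  if (is.null(newparams)) return(fitted(object))
  p <- as.data.frame(newparams)
  out <- vapply(seq_len(nrow(p)), function(i)
    model_pred(p$x[i], p$y[i], p$sigma[i], object$design),
    numeric(nrow(object$data)))
  drop(out)
}

#' Simulate BOLD series from a fitted pRF model
#'
#' Parametric simulation: fitted time course plus iid Gaussian noise with each
#' voxel's residual standard deviation.
#'
#' @param object a [prf_fit()] object.
#' @param nsim number of simulated datasets.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return a list of `nsim` matrices shaped like the data.
#' @export
simulate.prf_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  f <- as.matrix(fitted(object))
  r <- as.matrix(residuals(object))
  sds <- apply(r, 2, stats::sd)
  lapply(seq_len(nsim), function(i)
    f + matrix(stats::rnorm(length(f), sd = rep(sds, each = nrow(f))),
               nrow(f)))
}

#' @export
summary.prf_fit <- function(object, ve_threshold = 0.04, ...) {
  est <- object$estimates
  ok <- est$variance_explained >= ve_threshold & !est$no_signal
  out <- list(
    n_voxels = nrow(est),
    n_frames = nrow(object$data),
    n_candidates = nrow(object$design$grid),
    refine = object$refine,
    ve_threshold = ve_threshold,
    n_above = sum(ok),
    ve_quartiles = stats::quantile(est$variance_explained,
                                   c(0.25, 0.5, 0.75)),
    sigma_quartiles = stats::quantile(est$sigma[ok], c(0.25, 0.5, 0.75),
                                      na.rm = TRUE),
    ecc_range = if (any(ok)) range(est$eccentricity[ok]) else c(NA, NA))
  class(out) <- "summary.prf_fit"
  out
}

#' @export
print.summary.prf_fit <- function(x, ...) {
  cat("pRF model fit summary\n")
  cat(sprintf("  %d voxels x %d frames; bank of %d candidates%s\n",
              x$n_voxels, x$n_frames, x$n_candidates,
              if (x$refine) " + refinement" else ""))
  cat(sprintf("  %d voxels (%.0f%%) at variance explained >= %.2f\n",
              x$n_above, 100 * x$n_above / x$n_voxels, x$ve_threshold))
  cat("  variance explained quartiles: ",
      paste(sprintf("%.3f", x$ve_quartiles), collapse = " / "), "\n", sep = "")
  if (x$n_above > 0) {
    cat("  sigma quartiles (deg, thresholded): ",
        paste(sprintf("%.2f", x$sigma_quartiles), collapse = " / "),
        "\n", sep = "")
    cat(sprintf("  eccentricity range (thresholded): %.2f - %.2f deg\n",
                x$ecc_range[1], x$ecc_range[2]))
  }
  invisible(x)
}

#' Plot a pRF fit
#'
#' Two-panel base-graphics display: pRF centers in the visual field (point
#' size proportional to sigma, shaded by variance explained) and sigma versus
#' eccentricity for voxels above the variance-explained threshold.
#'
#' @param x a [prf_fit()] object.
#' @param ve_threshold display threshold on variance explained.
#' @param ... passed to [graphics::plot()].
#' @export
plot.prf_fit <- function(x, ve_threshold = 0.04, ...) {
  est <- x$estimates[!x$estimates$no_signal, ]
  est <- est[est$variance_explained >= ve_threshold, ]
  if (nrow(est) == 0) {
    warning("no voxels above threshold; nothing to plot")
    return(invisible(x))
  }
  r <- x$design$seq$field_radius
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  shade <- grDevices::gray(1 - pmin(est$variance_explained, 1) * 0.8)
  graphics::plot(est$x, est$y, asp = 1, xlim = c(-r, r), ylim = c(-r, r),
                 pch = 19, col = shade, cex = 0.5 + est$sigma / 4,
                 xlab = "x (deg)", ylab = "y (deg)",
                 main = "pRF centers", ...)
  graphics::symbols(0, 0, circles = r, inches = FALSE, add = TRUE,
                    fg = "gray")
  graphics::plot(est$eccentricity, est$sigma, pch = 19, col = shade,
                 xlab = "eccentricity (deg)", ylab = "sigma (deg)",
                 main = "pRF size vs eccentricity", ...)
  invisible(x)
}
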