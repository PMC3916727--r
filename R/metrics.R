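#' Variance explained by a predicted time course
#'
#' Fraction of the data variance captured by the prediction after fitting a
#' nonnegative amplitude and an intercept by least squares: 1 - RSS/TSS,
#' clipped to [0, 1]. A pRF predicts positive BOLD modulation, so predictions
#' that would require a negative amplitude score 0. Invariant to positive
#' rescaling and constant offsets of the data.
#'
#' @param pred predicted series.
#' @param data observed series (same length).
#' @return variance explained in [0, 1]. Zero-variance data are flagged with
#'   attribute `no_signal = TRUE` and return 0.
#' @export
variance_explained <- function(pred, data) {
  if (length(pred) != length(data))
    stop("pred and data must have equal length", call. = FALSE)
  sdd <- stats::sd(data)
  if (!is.finite(sdd) || sdd < 1e-12)
    return(structure(0, no_signal = TRUE))
  sdp <- stats::sd(pred)
  if (sdp < 1e-12) return(0)
  r <- stats::cor(pred, data)
  min(max(r, 0)^2, 1)
}

#' Convert between variance explained and coherence
#'
#' In traveling-wave retinotopy, goodness of fit is reported as coherence; in
#' pRF modeling, as variance explained. The two conventions correspond through
#' coherence = sqrt(variance explained), so the standard coherence threshold
#' of 0.20 matches a variance-explained threshold of 0.04. (The commonly
#' quoted baseline-noise pair 0.15 / 0.03 is approximate: 0.15^2 = 0.0225.)
#'
#' @param ve variance explained in [0, 1].
#' @param coh coherence in [0, 1].
#' @return the corresponding value on the other scale.
#' @export
ve_to_coherence <- function(ve) {
  if (any(ve < 0 | ve > 1)) stop("ve must lie in [0, 1]", call. = FALSE)
  sqrt(ve)
}

#' @rdname ve_to_coherence
#' @export
coherence_to_ve <- function(coh) {
  if (any(coh < 0 | coh > 1)) stop("coherence must lie in [0, 1]", call. = FALSE)
  coh^2
}

#' Eccentricity and polar angle of visual-field positions
#'
#' Derives polar visual-field coordinates from a pRF center: eccentricity is
#' the distance from fixation, sqrt(x^2 + y^2); polar angle is the
#' quadrant-aware two-argument arctangent of (y, x) in degrees, in
#' (-180, 180], with 0 on the right horizontal meridian and positive angles
#' in the upper visual field. The origin maps to (0, 0) by convention.
#'
#' @param x,y pRF center coordinates, degrees (vectorised).
#' @return a data.frame with columns `eccentricity` and `polar_angle`.
#' @export
ecc_angle <- function(x, y) {
  ecc <- sqrt(x^2 + y^2)
  ang <- atan2(y, x) * 180 / pi
  ang[ecc == 0] <- 0
  data.frame(eccentricity = ecc, polar_angle = ang)
}
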