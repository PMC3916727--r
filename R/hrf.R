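#' Hemodynamic response function parameters
#'
#' Parameter set for the canonical difference-of-gamma-densities HRF used to
#' convolve predicted neural responses into BOLD predictions. Gamma shapes are
#' parameterised as delay / dispersion with scale = dispersion, so the
#' response peaks near `peak_delay` and a later undershoot, scaled by
#' `undershoot_ratio`, peaks near `undershoot_delay`.
#'
#' @param peak_delay time-to-peak of the positive lobe, seconds.
#' @param undershoot_delay time-to-trough of the undershoot, seconds.
#' @param peak_dispersion width of the positive lobe, seconds.
#' @param undershoot_dispersion width of the undershoot, seconds.
#' @param undershoot_ratio undershoot amplitude relative to the peak;
#'   0 gives a single-gamma HRF.
#' @param kernel_length kernel support, seconds; must cover the undershoot
#'   (at least `undershoot_delay + 3 * undershoot_dispersion`).
#' @return an object of class `hrf_params`.
#' @examples
#' k <- hrf_kernel(hrf_params(), dt = 2)
#' (which.max(k) - 1) * 2   # sampled peak at 6 s
#' @export
hrf_params <- function(peak_delay = 6, undershoot_delay = 16,
                       peak_dispersion = 1, undershoot_dispersion = 1,
                       undershoot_ratio = 1 / 6, kernel_length = 32) {
  if (peak_dispersion <= 0 || undershoot_dispersion <= 0)
    stop("HRF dispersions must be positive", call. = FALSE)
  if (peak_delay <= 0 || undershoot_delay <= 0)
    stop("HRF delays must be positive", call. = FALSE)
  if (undershoot_ratio < 0)
    stop("undershoot_ratio must be nonnegative", call. = FALSE)
  if (kernel_length < undershoot_delay + 3 * undershoot_dispersion)
    stop("kernel_length too short to cover the undershoot", call. = FALSE)
  structure(list(peak_delay = peak_delay,
                 undershoot_delay = undershoot_delay,
                 peak_dispersion = peak_dispersion,
                 undershoot_dispersion = undershoot_dispersion,
                 undershoot_ratio = undershoot_ratio,
                 kernel_length = kernel_length),
            class = "hrf_params")
}

#' Sampled hemodynamic response kernel
#'
#' Evaluates the difference-of-gamma-densities HRF on a regular time grid
#' starting at t = 0, for use in discrete causal convolution.
#'
#' @param params an [hrf_params()] object.
#' @param dt sampling interval, seconds (typically the TR).
#' @return numeric kernel sampled at `0, dt, 2*dt, ...` up to `kernel_length`.
#' @export
hrf_kernel <- function(params = hrf_params(), dt) {
  stopifnot(inherits(params, "hrf_params"))
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  t <- seq(0, params$kernel_length, by = dt)
  peak <- stats::dgamma(t, shape = params$peak_delay / params$peak_dispersion,
                        scale = params$peak_dispersion)
  under <- stats::dgamma(t, shape = params$undershoot_delay / params$undershoot_dispersion,
                         scale = params$undershoot_dispersion)
  peak - params$undershoot_ratio * under
}

# causal discrete convolution truncated to the input length
convolve_hrf <- function(x, kernel) {
  n <- length(x)
  out <- stats::convolve(c(x, numeric(length(kernel))), rev(kernel),
                         type = "open")
  out[seq_len(n)]
}
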