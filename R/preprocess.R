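#' Polynomial detrending of BOLD time series
#'
#' Removes a least-squares polynomial trend from each voxel time series, the
#' high-pass step that strips scanner drift and slow physiological noise while
#' preserving stimulus-driven fluctuations (the bar sequence has no power
#' below 1 cycle/scan, and its blank structure sits at 4 cycles/scan, far
#' above the removed trend). Output is zero-mean by construction.
#'
#' @param ts numeric vector, or a frames x voxels matrix (each column one
#'   series).
#' @param order polynomial order (0 = mean removal, 1 = linear, ...).
#' @return detrended series, same shape as the input.
#' @export
detrend_ts <- function(ts, order = 2) {
  if (order < 0) stop("order must be nonnegative", call. = FALSE)
  m <- as.matrix(ts)
  n <- nrow(m)
  if (n <= order + 1)
    stop("series too short for a degree-", order, " trend", call. = FALSE)
  basis <- stats::poly(seq_len(n), degree = max(order, 1), raw = FALSE)
  if (order == 0) basis <- basis[, 0, drop = FALSE]
  fit <- stats::lm.fit(cbind(1, basis), m)
  res <- as.matrix(fit$residuals)
  if (is.matrix(ts)) res else drop(res)
}

#' Average repeated scans into one mean time series
#'
#' Pointwise mean of repeated (already detrended) scans of the same stimulus,
#' forming the single mean time series fitted per voxel. Independent noise
#' variance drops as 1/n.
#'
#' @param scans a list of equal-length numeric vectors (or matrices with
#'   matching dimensions), or a 3-d array with scans along the last margin.
#' @return the pointwise mean, shaped like one scan.
#' @export
average_scans <- function(scans) {
  if (is.array(scans) && length(dim(scans)) == 3)
    return(rowMeans(scans, dims = 2))
  stopifnot(is.list(scans), length(scans) >= 1)
  d <- if (is.matrix(scans[[1]])) dim(scans[[1]]) else length(scans[[1]])
  for (s in scans) {
    ds <- if (is.matrix(s)) dim(s) else length(s)
    if (!identical(ds, d)) stop("scans differ in shape", call. = FALSE)
  }
  Reduce(`+`, scans) / length(scans)
}
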