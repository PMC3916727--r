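#' Eccentricity-band regions of interest
#'
#' Contiguous half-open eccentricity intervals used as the unit of
#' visual-field-map analysis. The standard set is ten 1-degree bands covering
#' [0, 10) degrees, centered on every half degree (0.5, 1.5, ..., 9.5).
#'
#' @param lo,hi range covered, degrees.
#' @param width band width, degrees; must divide `hi - lo`.
#' @return a data.frame of class `ecc_bands` with columns `lo`, `hi`,
#'   `center`; bands are `[lo, hi)`.
#' @export
make_ecc_bands <- function(lo = 0, hi = 10, width = 1) {
  if (hi <= lo) stop("hi must exceed lo", call. = FALSE)
  n <- (hi - lo) / width
  if (abs(n - round(n)) > 1e-9)
    stop("width must divide the range (", hi - lo, " / ", width,
         " is not an integer)", call. = FALSE)
  n <- as.integer(round(n))
  edges <- lo + (0:n) * width
  out <- data.frame(lo = edges[-(n + 1)], hi = edges[-1],
                    center = edges[-(n + 1)] + width / 2)
  class(out) <- c("ecc_bands", "data.frame")
  out
}

# half-open band membership; values >= hi of the last band fall nowhere
band_index <- function(ecc, bands) {
  idx <- findInterval(ecc, c(bands$lo, bands$hi[nrow(bands)]),
                      rightmost.closed = FALSE)
  idx[idx < 1 | idx > nrow(bands) | ecc >= bands$hi[nrow(bands)]] <- NA_integer_
  idx
}

#' Band-wise statistics of pRF estimates on a cortical sheet
#'
#' Workhorse for the eccentricity-band profiles: assigns nodes to bands by
#' fitted eccentricity (half-open intervals; eccentricities at or beyond the
#' last band edge are excluded) and aggregates a statistic per (map, band).
#'
#' * `area_mm2` — summed cortical area of nodes at variance explained >=
#'   `ve_threshold` (sub-threshold nodes contribute nowhere).
#' * `mean_ve` — mean variance explained of all nodes, no threshold.
#' * `mean_sigma` — mean fitted sigma of nodes at or above the threshold.
#'
#' Empty bands are `NA` for mean statistics (flagged by `n_nodes = 0`), and 0
#' for area.
#'
#' @param nodes data.frame with columns `map_group` (or `map`),
#'   `eccentricity`, `variance_explained`, and `sigma` / `area` as required
#'   by the statistic.
#' @param bands an [make_ecc_bands()] object.
#' @param statistic one of "area_mm2", "mean_ve", "mean_sigma".
#' @param ve_threshold variance-explained inclusion threshold (default the
#'   conventional 0.04); ignored for `mean_ve`.
#' @return a data.frame `band_profile`: `map`, `band_center`, `statistic`,
#'   `value`, `n_nodes`.
#' @export
band_profile <- function(nodes, bands = make_ecc_bands(),
                         statistic = c("area_mm2", "mean_ve", "mean_sigma"),
                         ve_threshold = 0.04) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(bands, "ecc_bands"))
  map <- if ("map_group" %in% names(nodes)) nodes$map_group else nodes$map
  if (is.null(map)) stop("nodes need a `map` or `map_group` column",
                         call. = FALSE)
  need <- switch(statistic, area_mm2 = "area", mean_sigma = "sigma",
                 mean_ve = NULL)
  if (!is.null(need) && is.null(nodes[[need]]))
    stop("nodes lack the `", need, "` column required for ", statistic,
         call. = FALSE)
  keep <- if (statistic == "mean_ve") rep(TRUE, nrow(nodes))
          else nodes$variance_explained >= ve_threshold
  keep <- keep & !is.na(nodes$eccentricity)
  idx <- band_index(nodes$eccentricity, bands)
  keep <- keep & !is.na(idx)

  out <- expand.grid(band_center = bands$center, map = sort(unique(map)),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[, c("map", "band_center")]
  key <- interaction(map[keep], factor(idx[keep], levels = seq_len(nrow(bands))),
                     drop = FALSE)
  val <- switch(statistic,
                area_mm2 = nodes$area[keep],
                mean_ve = nodes$variance_explained[keep],
                mean_sigma = nodes$sigma[keep])
  counts <- table(factor(idx[keep], levels = seq_len(nrow(bands))), map[keep])
  out$n_nodes <- as.integer(counts[cbind(match(out$band_center, bands$center),
                                         match(out$map, colnames(counts)))])
  agg <- tapply(val, list(factor(idx[keep], levels = seq_len(nrow(bands))),
                          map[keep]),
                if (statistic == "area_mm2") sum else mean)
  out$value <- agg[cbind(match(out$band_center, bands$center),
                         match(out$map, colnames(agg)))]
  if (statistic == "area_mm2") out$value[is.na(out$value)] <- 0
  out$statistic <- statistic
  out <- out[, c("map", "band_center", "statistic", "value", "n_nodes")]
  class(out) <- c("band_profile", "data.frame")
  attr(out, "bands") <- bands
  attr(out, "ve_threshold") <- if (statistic == "mean_ve") NA else ve_threshold
  out
}

#' @rdname band_profile
#' @export
band_surface_area <- function(nodes, bands = make_ecc_bands(),
                              ve_threshold = 0.04) {
  band_profile(nodes, bands, "area_mm2", ve_threshold)
}

#' @rdname band_profile
#' @export
band_mean_ve <- function(nodes, bands = make_ecc_bands()) {
  band_profile(nodes, bands, "mean_ve")
}

#' @rdname band_profile
#' @export
band_mean_sigma <- function(nodes, bands = make_ecc_bands(),
                            ve_threshold = 0.04) {
  band_profile(nodes, bands, "mean_sigma", ve_threshold)
}

#' Surface-area percent distribution across eccentricity bands
#'
#' Normalizes a band area profile by total map surface area: 100 x band area
#' / summed area over the normalization set. By default normalization is over
#' all bands present in the profile (the whole thresholded map); for
#' comparison with conventional cortical-magnification displays, reporting is
#' often restricted to the bands centered 1.5-9.5 degrees via `include`, since
#' a bar stimulus measures neither the exact center of gaze nor the edge of
#' the mapped field cleanly.
#'
#' @param profile a `band_profile` of statistic `area_mm2`.
#' @param include band centers to report (default all).
#' @param normalize_over band centers forming the denominator (default all in
#'   the profile). When `normalize_over == include`, the reported percentages
#'   sum to 100 per map.
#' @return a `band_profile` with statistic `area_percent`. Maps with zero
#'   total area are flagged: their values are `NA` and listed in the
#'   `empty_maps` attribute.
#' @export
percent_distribution <- function(profile, include = NULL,
                                 normalize_over = NULL) {
  stopifnot(inherits(profile, "band_profile"),
            all(profile$statistic == "area_mm2"))
  if (is.null(include)) include <- unique(profile$band_center)
  if (is.null(normalize_over)) normalize_over <- unique(profile$band_center)
  totals <- tapply(profile$value[profile$band_center %in% normalize_over],
                   profile$map[profile$band_center %in% normalize_over], sum)
  out <- profile[profile$band_center %in% include, ]
  tot <- as.numeric(totals[match(out$map, names(totals))])
  out$value <- ifelse(tot > 0, 100 * out$value / tot, NA_real_)
  out$statistic <- "area_percent"
  empty <- names(totals)[totals <= 0]
  class(out) <- c("band_profile", "data.frame")
  attr(out, "empty_maps") <- empty
  out
}

#' Total thresholded surface area per visual field map
#'
#' Sum of node areas at variance explained >= `ve_threshold`, per map.
#'
#' @inheritParams band_profile
#' @return named numeric vector, mm^2 per map.
#' @export
total_map_area <- function(nodes, ve_threshold = 0.04) {
  map <- if ("map_group" %in% names(nodes)) nodes$map_group else nodes$map
  keep <- nodes$variance_explained >= ve_threshold
  out <- tapply(nodes$area[keep], factor(map[keep], levels = unique(map)), sum)
  out[is.na(out)] <- 0
  out
}
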