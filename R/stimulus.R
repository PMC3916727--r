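#' Moving-bar aperture sequence for visual field mapping
#'
#' Generates the binary stimulus aperture movie of a high-contrast bar that
#' steps across the visual field in eight configurations (four orientations,
#' two opposed sweep directions each), the standard stimulus for population
#' receptive field mapping. One full cycle consists of four equal periods;
#' within each period two configurations sweep and the final quarter of the
#' period is replaced by mean-luminance blanks, so blanks recur at four cycles
#' per sequence (a non-stimulus frequency usable for noise estimation).
#'
#' With the defaults (11 degree field radius, 2 s frames) the sequence is 96
#' frames / 192 s: four 48 s periods, each ending in 12 s (6 frames) of blank.
#' Each sweep nominally takes 12 steps to cross the full field diameter; the
#' second sweep of every period is truncated by the terminal blank after 6
#' steps. Because the truncated configurations appear with both sweep
#' directions across the cycle, the union of bar positions still covers the
#' whole field.
#'
#' The aperture grid is square with side `2 * field_radius`, cell centers at
#' regular spacing, x positive rightward, y positive upward, origin at
#' fixation. Apertures are binary: checkerboard contrast and flicker are not
#' modeled, since the pRF model is agnostic to the contrast pattern inside the
#' bar. Cells beyond `field_radius` from fixation are never switched on.
#'
#' Configuration order is fixed: orientations (measured as the bar's long axis
#' in degrees from vertical) are paired per period as (0, 90), (45, 135),
#' (0, 90), (135, 45) with the first two periods sweeping in the positive
#' normal direction and the last two in the negative. Any fixed order
#' preserves the model because fitting always uses the actual sequence.
#'
#' @param grid_resolution cells per side of the square aperture grid (>= 32).
#' @param field_radius stimulus extent from fixation, degrees of visual angle.
#' @param bar_width bar width in degrees; default `field_radius / 4`.
#' @param frame_duration seconds per frame (the TR); must divide both the 48 s
#'   period and its 12 s terminal blank.
#'
#' @return An object of class `aperture_sequence`: a list with `masks` (frames
#'   x cells binary matrix), `x`, `y` (cell-center coordinates, degrees),
#'   `n_grid`, `field_radius`, `frame_duration`, `blank` (per-frame logical),
#'   `config_index` (per-frame integer 1..8, `NA` on blanks), and `n_frames`.
#' @examples
#' seq <- make_bar_sequence(grid_resolution = 51)
#' sum(!seq$blank) * seq$frame_duration  # stimulated seconds per cycle
#' @export
make_bar_sequence <- function(grid_resolution = 101, field_radius = 11,
                              bar_width = field_radius / 4,
                              frame_duration = 2) {
  if (grid_resolution < 32)
    stop("grid_resolution must be at least 32", call. = FALSE)
  if (field_radius <= 0)
    stop("field_radius must be positive", call. = FALSE)
  if (bar_width <= 0 || bar_width >= 2 * field_radius)
    stop("bar_width must lie strictly between 0 and the field diameter",
         call. = FALSE)
  if (frame_duration <= 0)
    stop("frame_duration must be positive", call. = FALSE)
  period_s <- 48
  blank_s <- 12
  if (abs(period_s / frame_duration - round(period_s / frame_duration)) > 1e-9 ||
      abs(blank_s / frame_duration - round(blank_s / frame_duration)) > 1e-9)
    stop("frame_duration must divide the 48 s period and its 12 s blank",
         call. = FALSE)

  n_per_period <- as.integer(round(period_s / frame_duration))
  n_blank <- as.integer(round(blank_s / frame_duration))
  n_steps <- n_per_period %/% 2L      # nominal steps per sweep (12 at TR = 2)
  step <- 2 * field_radius / n_steps

  ctr <- seq(-field_radius, field_radius, length.out = grid_resolution)
  gx <- rep(ctr, times = grid_resolution)
  gy <- rep(ctr, each = grid_resolution)
  in_field <- sqrt(gx^2 + gy^2) <= field_radius + 1e-12

  # (orientation from vertical, sweep direction sign), two configs per period
  configs <- data.frame(
    orientation = c(0, 90, 45, 135, 0, 90, 135, 45),
    direction   = c(1, 1, 1, 1, -1, -1, -1, -1)
  )

  n_frames <- 4L * n_per_period
  masks <- matrix(0, nrow = n_frames, ncol = grid_resolution^2)
  blank <- logical(n_frames)
  config_index <- rep(NA_integer_, n_frames)

  frame <- 0L
  for (period in 1:4) {
    for (slot in 1:2) {
      cfg <- 2L * (period - 1L) + slot
      th <- configs$orientation[cfg] * pi / 180
      # bar long axis at `th` from vertical; sweep along the unit normal
      proj <- gx * cos(th) - gy * sin(th)
      offsets <- -field_radius + (seq_len(n_steps) - 0.5) * step
      if (configs$direction[cfg] < 0) offsets <- rev(offsets)
      for (i in seq_len(n_steps)) {
        frame <- frame + 1L
        if (frame > period * n_per_period - n_blank) next  # blank tail
        on <- in_field & abs(proj - offsets[i]) <= bar_width / 2
        masks[frame, on] <- 1
        config_index[frame] <- cfg
      }
    }
    blank_idx <- (period * n_per_period - n_blank + 1L):(period * n_per_period)
    blank[blank_idx] <- TRUE
    frame <- period * n_per_period
  }

  structure(list(masks = masks, x = gx, y = gy,
                 n_grid = as.integer(grid_resolution),
                 field_radius = field_radius,
                 bar_width = bar_width,
                 frame_duration = frame_duration,
                 blank = blank, config_index = config_index,
                 n_frames = n_frames),
            class = "aperture_sequence")
}

#' Per-frame overlap of an aperture sequence with a visual-field weight map
#'
#' Computes, for every frame, the sum over grid cells of aperture mask times
#' weight. This is the inner-product step of the pRF forward prediction: with
#' a Gaussian weight map it gives the stimulus drive to that pRF at each
#' frame. Blank frames yield exactly zero.
#'
#' @param seq an [make_bar_sequence()] object.
#' @param weights numeric weight map on the sequence's grid: either a vector
#'   of length `n_grid^2` (cell order matching `seq$x`/`seq$y`) or an
#'   `n_grid` x `n_grid` matrix.
#' @return numeric vector, one value per frame.
#' @export
aperture_overlap <- function(seq, weights) {
  stopifnot(inherits(seq, "aperture_sequence"))
  w <- as.numeric(weights)
  if (length(w) != ncol(seq$masks))
    stop("weight map does not match the aperture grid (expected ",
         ncol(seq$masks), " cells, got ", length(w), ")", call. = FALSE)
  as.numeric(seq$masks %*% w)
}

#' @export
print.aperture_sequence <- function(x, ...) {
  cat("Moving-bar aperture sequence\n")
  cat(sprintf("  %d frames x %.0f s = %.0f s total; grid %dx%d; field radius %g deg\n",
              x$n_frames, x$frame_duration, x$n_frames * x$frame_duration,
              x$n_grid, x$n_grid, x$field_radius))
  cat(sprintf("  bar width %.3g deg; %d blank frames in %d runs\n",
              x$bar_width, sum(x$blank),
              sum(diff(c(FALSE, x$blank)) == 1)))
  invisible(x)
}

#' @export
plot.aperture_sequence <- function(x, frame = 1, ...) {
  m <- matrix(x$masks[frame, ], x$n_grid, x$n_grid)
  graphics::image(unique(x$x), unique(x$y), m, asp = 1,
                  xlab = "x (deg)", ylab = "y (deg)",
                  main = sprintf("frame %d%s", frame,
                                 if (x$blank[frame]) " (blank)" else ""),
                  col = grDevices::gray(c(0.5, 1)), ...)
  invisible(x)
}
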