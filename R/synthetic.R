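#' Scenario configuration for synthetic retinotopic cortex
#'
#' Bundles every constant needed to generate a synthetic cortical sheet with
#' known pRF ground truth and to simulate BOLD responses from it. The four
#' presets encode the study conditions the generator emulates:
#'
#' * `young` — the template: complex-log eccentricity mapping (foveal
#'   over-representation), linear sigma-vs-eccentricity laws per map.
#' * `aging` — the young template with the cortical area of the central 3
#'   degrees shrunk (`foveal_area_scale`) and foveal pRFs enlarged
#'   (`foveal_sigma_scale`, calibrated so mean ground-truth V1 sigma in the
#'   most foveal band is about 2 degrees).
#' * `ad_scrambled` — eccentricity assignments permuted in cortical patches
#'   (polar angle untouched) and response amplitude halved, emulating patchy,
#'   disordered eccentricity maps with reduced variance explained.
#' * `ad_truncated` — eccentricity compressed into `[0, peripheral_cutoff]`,
#'   emulating maps lacking the expected peripheral representation.
#'
#' The eccentricity template along the cortical axis u is
#' `ecc(u) = a * (exp(u / k) - 1)`, with `k` set per map so the full field
#' radius is reached at the map's cortical length (`v1_length_mm` for V1,
#' scaled by `map_length_scale` for the rest). Polar angle is linear along
#' the orthogonal axis v, spanning a hemifield for V1 and hV4 and a
#' quarterfield for each V2/V3 component. pRF spread follows
#' `sigma = slope * ecc + intercept` per map, with slopes/intercepts ordered
#' V1 < V2 < V3 < hV4 as in published size-vs-eccentricity measurements.
#'
#' Noise for [simulate_bold()] is AR(1) Gaussian plus a slow polynomial
#' drift; `amplitude / noise$sd` is the per-scan SNR (default 1 / 0.2 = 5).
#'
#' @param name one of "young", "aging", "ad_scrambled", "ad_truncated".
#' @param field_radius mapped field extent, degrees.
#' @param a,v1_length_mm complex-log template constants: foveal offset
#'   (degrees) and V1 cortical length (mm) covering the field.
#' @param map_length_scale named cortical length scales relative to V1.
#' @param sigma_law named list of `c(slope, intercept)` per map group.
#' @param foveal_limit eccentricity bound of the "foveal" zone, degrees.
#' @param foveal_area_scale,foveal_sigma_scale aging perturbations applied to
#'   nodes below `foveal_limit`.
#' @param scramble_patch_size cortical patch size (mm) for `ad_scrambled`.
#' @param peripheral_cutoff maximum represented eccentricity for
#'   `ad_truncated`, degrees.
#' @param amplitude response amplitude in percent-signal units (signal SD per
#'   scan); `ad_scrambled` halves it.
#' @param noise list with `sd` (marginal noise SD), `ar1` (lag-1
#'   autocorrelation), `drift_amplitude` (slow drift scale).
#' @param n_u,n_v V1 lattice size along the eccentricity / polar-angle axes;
#'   other maps scale `n_u` by their length scale and use half `n_v` per
#'   quarterfield component.
#' @param subject_jitter_sd SD of the multiplicative lognormal jitter applied
#'   to template constants per simulated subject.
#' @param seed RNG seed stored with the config; identical configs generate
#'   identical datasets.
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(name = c("young", "aging", "ad_scrambled",
                                     "ad_truncated"),
                            field_radius = 11, a = 0.75, v1_length_mm = 40,
                            map_length_scale = c(V1 = 1, V2 = 0.8, V3 = 0.7,
                                                 hV4 = 0.5),
                            sigma_law = list(V1 = c(0.10, 0.5),
                                             V2 = c(0.15, 0.7),
                                             V3 = c(0.20, 0.9),
                                             hV4 = c(0.25, 1.1)),
                            foveal_limit = 3,
                            foveal_area_scale = if (name == "aging") 0.6 else 1,
                            foveal_sigma_scale = if (name == "aging") 3.6 else 1,
                            scramble_patch_size = 4,
                            peripheral_cutoff = if (name == "ad_truncated") 5
                                                else field_radius,
                            amplitude = if (name == "ad_scrambled") 0.5 else 1,
                            noise = list(sd = 0.2, ar1 = 0.3,
                                         drift_amplitude = 0.5),
                            n_u = 20, n_v = 6,
                            subject_jitter_sd = 0.1, seed = 1L) {
  name <- match.arg(name)
  if (a <= 0 || v1_length_mm <= 0)
    stop("template constants a and v1_length_mm must be positive",
         call. = FALSE)
  if (foveal_area_scale <= 0 || foveal_sigma_scale <= 0)
    stop("foveal scales must be positive", call. = FALSE)
  if (peripheral_cutoff > field_radius || peripheral_cutoff <= 0)
    stop("peripheral_cutoff must lie in (0, field_radius]", call. = FALSE)
  stopifnot(all(c("V1", "V2", "V3", "hV4") %in% names(map_length_scale)),
            all(c("V1", "V2", "V3", "hV4") %in% names(sigma_law)))
  structure(list(name = name, field_radius = field_radius, a = a,
                 v1_length_mm = v1_length_mm,
                 map_length_scale = map_length_scale, sigma_law = sigma_law,
                 foveal_limit = foveal_limit,
                 foveal_area_scale = foveal_area_scale,
                 foveal_sigma_scale = foveal_sigma_scale,
                 scramble_patch_size = scramble_patch_size,
                 peripheral_cutoff = peripheral_cutoff,
                 amplitude = amplitude, noise = noise,
                 n_u = n_u, n_v = n_v,
                 subject_jitter_sd = subject_jitter_sd,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

# component maps: parent group, polar-angle span (left hemisphere =
# contralateral right hemifield; angles in degrees), physical width (mm),
# lattice v points relative to n_v
map_components <- function() {
  data.frame(
    map = c("V1", "V2d", "V2v", "V3d", "V3v", "hV4"),
    group = c("V1", "V2", "V2", "V3", "V3", "hV4"),
    ang_lo = c(-90, -90, 0, -90, 0, -90),
    ang_hi = c(90, 0, 90, 0, 90, 90),
    width_mm = c(30, 12, 12, 10, 10, 15),
    v_frac = c(1, 0.5, 0.5, 0.5, 0.5, 1))
}

#' Build a synthetic cortical sheet with ground-truth retinotopy
#'
#' Lays nodes on a regular cortical lattice for V1, V2 (dorsal/ventral), V3
#' (dorsal/ventral) and hV4 in both hemispheres, assigns each node a
#' ground-truth pRF (center, spread, amplitude) from the scenario's
#' retinotopic template, and a cortical surface area (mm^2). Equal cortical
#' steps map onto exponentially growing eccentricity, so the fovea is
#' over-represented in cortex (cortical magnification). Each hemisphere
#' represents the contralateral hemifield; quarterfield components of V2/V3
#' mirror across the V1 border as in real maps.
#'
#' Scenario perturbations (aging foveal shrink/enlargement, AD-like
#' eccentricity scrambling or truncation) are applied as described in
#' [scenario_config()]. Generation is deterministic given the config
#' (including its seed, used only by the scrambling permutation).
#'
#' @param config a [scenario_config()].
#' @return a data.frame of class `cortical_sheet`, one row per node, with
#'   columns `node`, `hemisphere`, `map` (component), `map_group`, `u`, `v`
#'   (cortical coordinates, mm), `area` (mm^2), `truth_x`, `truth_y`,
#'   `truth_sigma` (deg), `truth_amplitude`, `truth_ecc`, `truth_angle`.
#' @examples
#' sheet <- build_sheet(scenario_config("young"))
#' tapply(sheet$area, sheet$map_group, sum)
#' @export
build_sheet <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  comp <- map_components()
  out <- list()
  for (hemi in c("L", "R")) {
    for (i in seq_len(nrow(comp))) {
      len <- config$v1_length_mm * config$map_length_scale[[comp$group[i]]]
      k <- len / log(1 + config$field_radius / config$a)
      nu <- max(2L, round(config$n_u * config$map_length_scale[[comp$group[i]]]))
      nv <- max(2L, round(config$n_v * comp$v_frac[i]))
      du <- len / nu
      dv <- comp$width_mm[i] / nv
      u <- (seq_len(nu) - 0.5) * du
      v <- (seq_len(nv) - 0.5) * dv
      g <- expand.grid(u = u, v = v, KEEP.OUT.ATTRS = FALSE)
      ecc <- config$a * (exp(g$u / k) - 1)
      ang <- comp$ang_lo[i] +
        (g$v - min(v)) / max(diff(range(v)), dv) *
          (comp$ang_hi[i] - comp$ang_lo[i])
      if (hemi == "R") {            # right hemisphere: left hemifield
        ang <- 180 - ang
        ang <- ifelse(ang > 180, ang - 360, ang)
      }
      law <- config$sigma_law[[comp$group[i]]]
      sheet <- data.frame(hemisphere = hemi, map = comp$map[i],
                          map_group = comp$group[i],
                          u = g$u, v = g$v, area = du * dv,
                          truth_ecc = ecc, truth_angle = ang,
                          truth_sigma = law[1] * ecc + law[2],
                          truth_amplitude = config$amplitude)
      out[[length(out) + 1]] <- sheet
    }
  }
  sheet <- do.call(rbind, out)

  fov <- sheet$truth_ecc < config$foveal_limit
  if (config$name == "aging") {
    sheet$area[fov] <- sheet$area[fov] * config$foveal_area_scale
    sheet$truth_sigma[fov] <- sheet$truth_sigma[fov] * config$foveal_sigma_scale
  }
  if (config$name == "ad_scrambled") {
    sheet <- scramble_eccentricity(sheet, config)
  }
  if (config$name == "ad_truncated") {
    sheet$truth_ecc <- sheet$truth_ecc *
      config$peripheral_cutoff / max(sheet$truth_ecc)
  }

  th <- sheet$truth_angle * pi / 180
  sheet$truth_x <- sheet$truth_ecc * cos(th)
  sheet$truth_y <- sheet$truth_ecc * sin(th)
  sheet$node <- seq_len(nrow(sheet))
  sheet <- sheet[, c("node", "hemisphere", "map", "map_group", "u", "v",
                     "area", "truth_x", "truth_y", "truth_sigma",
                     "truth_amplitude", "truth_ecc", "truth_angle")]
  class(sheet) <- c("cortical_sheet", "data.frame")
  attr(sheet, "config") <- config
  sheet
}

# permute eccentricity between equal-width cortical patches along u, within
# each (hemisphere, map) component; polar angle is left untouched
scramble_eccentricity <- function(sheet, config) {
  rng <- local({ set.seed(config$seed); function(n) sample.int(n) })
  for (hemi in unique(sheet$hemisphere)) {
    for (m in unique(sheet$map)) {
      idx <- which(sheet$hemisphere == hemi & sheet$map == m)
      u <- sheet$u[idx]
      len <- max(u) + min(u)                 # cell centers span (0, len)
      n_patch <- max(2L, round(len / config$scramble_patch_size))
      wid <- len / n_patch
      pid <- pmin(floor(u / wid) + 1L, n_patch)
      perm <- rng(n_patch)
      u_new <- (perm[pid] - 1L) * wid + (u - (pid - 1L) * wid)
      k <- len / log(1 + config$field_radius / config$a)
      sheet$truth_ecc[idx] <- config$a * (exp(u_new / k) - 1)
    }
  }
  sheet
}

#' Simulate BOLD scans from a synthetic cortical sheet
#'
#' Generative forward model for every node: ground-truth pRF prediction under
#' the stimulus (unit-variance normalized, scaled by the node's amplitude so
#' amplitude is the per-scan signal SD in percent-signal units), plus AR(1)
#' Gaussian noise and a slow random polynomial drift per scan. Returns raw
#' (undetrended) series. Fully reproducible from `(config, seed)`.
#'
#' @param sheet a [build_sheet()] cortical sheet.
#' @param seq an [make_bar_sequence()] aperture sequence.
#' @param hrf an [hrf_params()] object.
#' @param n_scans number of repeated scans.
#' @param config the sheet's [scenario_config()] (noise model, amplitude).
#' @param seed RNG seed; defaults to the config's.
#' @param target_snr optional per-node SNR override: noise SD is set to
#'   (signal SD)/`target_snr` for every responsive node.
#' @return a frames x nodes x scans array.
#' @export
simulate_bold <- function(sheet, seq, hrf = hrf_params(), n_scans = 1,
                          config = attr(sheet, "config"), seed = NULL,
                          target_snr = NULL) {
  stopifnot(inherits(sheet, "cortical_sheet"),
            inherits(seq, "aperture_sequence"), n_scans >= 1)
  if (is.null(config)) stop("sheet carries no config; supply one",
                            call. = FALSE)
  set.seed(if (is.null(seed)) config$seed else seed)
  n_nodes <- nrow(sheet)
  n <- seq$n_frames
  kernel <- hrf_kernel(hrf, dt = seq$frame_duration)
  cmat <- conv_matrix(kernel, n)

  w <- exp(-(outer(seq$x, sheet$truth_x, "-")^2 +
               outer(seq$y, sheet$truth_y, "-")^2) /
             (2 * rep(sheet$truth_sigma^2, each = length(seq$x))))
  signal <- cmat %*% (seq$masks %*% w)
  sds <- apply(signal, 2, stats::sd)
  scale <- ifelse(sds > 1e-12, sheet$truth_amplitude / pmax(sds, 1e-12), 0)
  signal <- sweep(signal, 2, scale, `*`)

  noise_sd <- rep(config$noise$sd, n_nodes)
  if (!is.null(target_snr))
    noise_sd <- ifelse(sheet$truth_amplitude > 0,
                       sheet$truth_amplitude / target_snr, config$noise$sd)

  tt <- seq_len(n) / n
  out <- array(0, dim = c(n, n_nodes, n_scans))
  for (s in seq_len(n_scans)) {
    innov <- matrix(stats::rnorm(n * n_nodes), n, n_nodes)
    ar <- apply(innov, 2, function(e)
      stats::filter(e, config$noise$ar1, method = "recursive"))
    ar <- ar * sqrt(1 - config$noise$ar1^2)
    ar <- sweep(ar, 2, noise_sd, `*`)
    b <- matrix(stats::rnorm(2 * n_nodes), 2, n_nodes)
    drift <- config$noise$drift_amplitude *
      (outer(tt, b[1, ]) + outer(tt^2, b[2, ]))
    out[, , s] <- signal + ar + drift
  }
  out
}

#' Per-subject jitter of a scenario configuration
#'
#' Applies multiplicative lognormal jitter (SD `subject_jitter_sd`) to the
#' template constants — foveal offset `a`, cortical length, and the sigma-law
#' slopes and intercepts — producing the between-subject variability of a
#' simulated cohort. Deterministic given `subject_seed`.
#'
#' @param config a [scenario_config()].
#' @param subject_seed integer seed identifying the subject.
#' @return a jittered `scenario_config` whose `seed` is `subject_seed`.
#' @export
jitter_config <- function(config, subject_seed) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(subject_seed)
  jit <- function(x) x * exp(stats::rnorm(length(x), 0, config$subject_jitter_sd))
  config$a <- jit(config$a)
  config$v1_length_mm <- jit(config$v1_length_mm)
  config$sigma_law <- lapply(config$sigma_law, jit)
  config$seed <- as.integer(subject_seed)
  config
}

#' Treat a sheet's ground truth as a perfect set of pRF estimates
#'
#' Recasts the ground-truth pRF parameters of a synthetic cortical sheet as a
#' node table in the shape the band-profile functions expect (`eccentricity`,
#' `sigma`, `variance_explained`, `area`, ...). Useful for analysing the
#' generative model itself — e.g. profiles a noiseless, error-free experiment
#' would measure — and as the fast path for large calibration studies that do
#' not need the BOLD simulation stage.
#'
#' @param sheet a [build_sheet()] cortical sheet.
#' @param ve variance explained to assign every node (default 1).
#' @return a data.frame with the sheet's columns plus `x`, `y`, `sigma`,
#'   `eccentricity`, `polar_angle`, `variance_explained` copied from truth.
#' @export
truth_estimates <- function(sheet, ve = 1) {
  stopifnot(inherits(sheet, "cortical_sheet"))
  out <- as.data.frame(sheet)
  out$x <- out$truth_x
  out$y <- out$truth_y
  out$sigma <- out$truth_sigma
  out$eccentricity <- out$truth_ecc
  out$polar_angle <- out$truth_angle
  out$variance_explained <- ve
  out
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("Scenario '%s': field %g deg, V1 %g mm, a = %g deg\n",
              x$name, x$field_radius, x$v1_length_mm, x$a))
  cat(sprintf("  amplitude %g, noise sd %g (SNR %g), AR1 %g, drift %g\n",
              x$amplitude, x$noise$sd, x$amplitude / x$noise$sd,
              x$noise$ar1, x$noise$drift_amplitude))
  if (x$name == "aging")
    cat(sprintf("  foveal (<%g deg) area x%g, sigma x%g\n", x$foveal_limit,
                x$foveal_area_scale, x$foveal_sigma_scale))
  if (x$name == "ad_scrambled")
    cat(sprintf("  eccentricity scrambled in %g mm patches\n",
                x$scramble_patch_size))
  if (x$name == "ad_truncated")
    cat(sprintf("  eccentricity truncated at %g deg\n", x$peripheral_cutoff))
  invisible(x)
}
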