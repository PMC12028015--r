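# Synthetic two-channel section generator. Emulates the statistical
# structure the downstream analysis assumes: per-region Poisson neuron
# counts, an injury survival gradient over rostro-caudal distance,
# section-level staining gain, neuronal-channel-only artifacts
# (autofluorescence stand-ins, no nuclear colocalization), additive noise,
# and imperfect observers (misses, false positives, localization jitter).
# Every stage is reproducible from a single integer seed.

# Deterministic child seed so stages can be re-run independently.
.child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(offset)) %% 2147483647)
}

#' Simulation configuration
#'
#' Parameters of the synthetic section generator. Defaults describe an
#' uninjured thoracic section calibrated to ~283 neurons (a typical
#' control-section count) with soma radii 5 ± 0.8 µm (truncated at 3.5 µm
#' so every soma clears the 25 µm² detection filter by construction) and a
#' survival gradient that falls to ~2.3% of control at 0.6 mm caudal to
#' the injury epicenter and recovers by ~20 percentage points per 200 µm to
#' a 40% plateau at 1.0–1.2 mm.
#'
#' @param pixel_size_um microns per pixel (> 0).
#' @param densities named vector, neurons per mm² per region; `NULL` uses
#'   [default_densities()] on the atlas at simulation time.
#' @param soma_radius_mean_um,soma_radius_sd_um,soma_radius_min_um soma
#'   radius distribution (normal, truncated below at the minimum).
#' @param survival_points two-column matrix `(distance_mm, fraction)`
#'   through which the overall survival curve is interpolated piecewise
#'   linearly (constant beyond the ends).
#' @param region_class_factors named multipliers (`dorsal`,
#'   `intermediate`, `ventral`) modulating survival by region class; they
#'   are renormalized at simulation time so the density-weighted mean
#'   survival equals the overall curve.
#' @param staining_gain_sd log-normal sd of the per-section multiplicative
#'   staining gain.
#' @param artifact_rate artifacts per mm² of frame (bright in the neuronal
#'   channel, no nuclear counterpart).
#' @param artifact_radius_um length-2 range of artifact radii (µm).
#' @param noise_sd additive Gaussian noise per channel (intensity units,
#'   images live in \[0, 1\]).
#' @param psf_sigma_px Gaussian point-spread sigma in pixels (0 = none).
#' @param intensities named list of rendering intensities
#'   (`neuron`, `nucleus`, `artifact`, `background`).
#' @param seed integer master seed.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(pixel_size_um = 2,
                              densities = NULL,
                              soma_radius_mean_um = 5,
                              soma_radius_sd_um = 0.8,
                              soma_radius_min_um = 3.5,
                              survival_points = cbind(
                                distance_mm = c(0.6, 0.8, 1.0, 1.2),
                                fraction = c(0.023, 0.20, 0.40, 0.40)),
                              region_class_factors = c(dorsal = 1.5,
                                                       intermediate = 0.6,
                                                       ventral = 1.0),
                              staining_gain_sd = 0.15,
                              artifact_rate = 2,
                              artifact_radius_um = c(3.5, 7),
                              noise_sd = 0.02,
                              psf_sigma_px = 1,
                              intensities = list(neuron = 0.8, nucleus = 0.7,
                                                 artifact = 0.85,
                                                 background = 0.05),
                              seed = 1L) {
  cfg <- structure(as.list(environment()), class = "simulation_config")
  validate_simulation_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' @param cfg a `simulation_config`.
#' @return `cfg` invisibly; errors on invalid fields.
#' @export
validate_simulation_config <- function(cfg) {
  stopifnot(cfg$pixel_size_um > 0)
  nonneg <- c("soma_radius_sd_um", "staining_gain_sd", "artifact_rate",
              "noise_sd", "psf_sigma_px")
  for (f in nonneg) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0) stop("`", f, "` must be >= 0")
  }
  if (!is.null(cfg$densities) && any(cfg$densities < 0)) {
    stop("densities must be >= 0")
  }
  sp <- cfg$survival_points
  if (any(sp[, 2] < 0 | sp[, 2] > 1)) {
    stop("survival fractions must lie in [0, 1]")
  }
  if (cfg$soma_radius_min_um <= 0 || cfg$soma_radius_mean_um <= 0) {
    stop("soma radii must be positive")
  }
  invisible(cfg)
}

#' Overall survival fraction at a distance from the injury epicenter
#'
#' Piecewise-linear interpolation through the configured anchor points,
#' constant beyond the first and last anchors. `NULL`/`NA` distance means
#' an uninjured control section (survival 1).
#'
#' @param config a `simulation_config`.
#' @param distance_mm rostro-caudal distance to the epicenter in mm, or
#'   `NULL`/`NA` for control.
#' @return Survival fraction in \[0, 1\].
#' @export
survival_fraction <- function(config, distance_mm) {
  if (is.null(distance_mm) || is.na(distance_mm)) return(1)
  sp <- config$survival_points
  stats::approx(sp[, 1], sp[, 2], xout = distance_mm, rule = 2)$y
}

#' Per-region survival fractions
#'
#' Applies the region-class factors to the overall curve, renormalized so
#' the density-weighted mean over the atlas equals the overall fraction
#' (section totals follow the overall gradient while dorsal laminae are
#' relatively spared and the intermediate grey is hit hardest).
#'
#' @param atlas a `toy_atlas`.
#' @param config a `simulation_config`.
#' @param distance_mm distance in mm or `NULL` for control.
#' @return Named vector of survival fractions per region, clamped to \[0, 1\].
#' @export
region_survival_fractions <- function(atlas, config, distance_mm) {
  ids <- atlas$region_info$region_id
  s <- survival_fraction(config, distance_mm)
  if (s == 1) return(stats::setNames(rep(1, length(ids)), ids))
  dens <- .resolve_densities(atlas, config)
  f <- unname(config$region_class_factors[atlas$region_info$class])
  w <- dens * region_areas(atlas)
  f <- f / sum(w * f) * sum(w)          # density-weighted mean factor = 1
  stats::setNames(pmin(1, pmax(0, s * f)), ids)
}

.resolve_densities <- function(atlas, config) {
  ids <- atlas$region_info$region_id
  if (is.null(config$densities)) {
    return(default_densities(atlas))
  }
  if (is.null(names(config$densities))) {
    if (length(config$densities) == 1L) {
      return(stats::setNames(rep(config$densities, length(ids)), ids))
    }
    stop("`densities` must be named by region_id (or a single value)")
  }
  missing <- setdiff(ids, names(config$densities))
  if (length(missing)) stop("densities missing for regions: ",
                            paste(missing, collapse = ", "))
  config$densities[ids]
}

# Linear indices of the pixels whose centers fall inside a disc of center
# (x, y) µm and radius r, for an h x w raster at pixel size s. Pixel
# (i, j) has center ((j-.5)s, (i-.5)s).
.disc_pixels <- function(x, y, r, s, h, w) {
  j0 <- max(1L, floor((x - r) / s + 0.5)); j1 <- min(w, ceiling((x + r) / s + 0.5))
  i0 <- max(1L, floor((y - r) / s + 0.5)); i1 <- min(h, ceiling((y + r) / s + 0.5))
  if (j0 > j1 || i0 > i1) return(integer(0))
  jj <- j0:j1; ii <- i0:i1
  px <- (jj - 0.5) * s; py <- (ii - 0.5) * s
  d2 <- outer((py - y)^2, (px - x)^2, "+")
  hit <- which(d2 <= r^2, arr.ind = TRUE)
  (jj[hit[, 2]] - 1L) * h + ii[hit[, 1]]
}

# Paint a filled disc (max-composited) into matrix `img`.
.paint_disc <- function(img, x, y, r, s, value) {
  idx <- .disc_pixels(x, y, r, s, nrow(img), ncol(img))
  img[idx] <- pmax(img[idx], value)
  img
}

# Logical mask of pixels whose centers fall inside any neuron soma.
.truth_disc_mask <- function(truth, dim_hw, pixel_size_um) {
  mm <- matrix(FALSE, dim_hw[1], dim_hw[2])
  nx <- truth$neurons$x; ny <- truth$neurons$y
  nr <- truth$neurons$soma_radius_um
  for (i in seq_along(nx)) {
    mm[.disc_pixels(nx[i], ny[i], nr[i], pixel_size_um,
                    dim_hw[1], dim_hw[2])] <- TRUE
  }
  mm
}

#' Simulate one two-channel section with ground truth
#'
#' Draws per-region neuron counts as Poisson(density × area × survival),
#' places somas uniformly in their region polygons, renders each as a disc
#' in the neuronal channel with a colocalized (smaller) nuclear disc,
#' renders artifacts in the neuronal channel only, applies a per-section
#' log-normal staining gain, an optional Gaussian PSF blur, and additive
#' noise. Fully reproducible from `seed`.
#'
#' @param atlas a `toy_atlas`.
#' @param config a `simulation_config`.
#' @param distance_mm distance to the injury epicenter in mm, or `NULL`
#'   for an uninjured control section.
#' @param section_id,condition metadata carried into image and truth.
#' @param seed overrides `config$seed` when given.
#' @return List with `image` (a `section_image`: `neuronal` and `nuclear`
#'   matrices in \[0, 1\], `pixel_size_um`, metadata) and `truth` (a
#'   `ground_truth`: `neurons` data.frame `x, y, region_id,
#'   soma_radius_um`; `artifacts` data.frame `x, y, radius_um`).
#' @export
simulate_section <- function(atlas, config, distance_mm = NULL,
                             section_id = "S1", condition = NULL,
                             seed = NULL) {
  validate_simulation_config(config)
  if (is.null(seed)) seed <- config$seed
  set.seed(seed)
  if (is.null(condition)) {
    condition <- if (is.null(distance_mm) || is.na(distance_mm))
      "control" else "injury"
  }
  s <- config$pixel_size_um
  W <- atlas$frame_um[["width"]]; H <- atlas$frame_um[["height"]]
  h <- as.integer(round(H / s)); w <- as.integer(round(W / s))

  dens <- .resolve_densities(atlas, config)
  surv <- region_survival_fractions(atlas, config, distance_mm)
  areas_mm2 <- region_areas(atlas) / 1e6
  ids <- atlas$region_info$region_id

  neurons <- list()
  for (id in ids) {
    lambda <- dens[[id]] * areas_mm2[[id]] * surv[[id]]
    n <- stats::rpois(1L, lambda)
    pts <- .sample_points_in_polygon(n, atlas$regions[[id]])
    r <- stats::rnorm(n, config$soma_radius_mean_um, config$soma_radius_sd_um)
    r <- pmax(r, config$soma_radius_min_um)
    neurons[[id]] <- data.frame(x = pts[, 1], y = pts[, 2],
                                region_id = rep(id, n),
                                soma_radius_um = r,
                                stringsAsFactors = FALSE)
  }
  neurons <- do.call(rbind, neurons)
  rownames(neurons) <- NULL

  n_art <- stats::rpois(1L, config$artifact_rate * (W * H / 1e6))
  artifacts <- data.frame(
    x = stats::runif(n_art, 0, W),
    y = stats::runif(n_art, 0, H),
    radius_um = stats::runif(n_art, config$artifact_radius_um[1],
                             config$artifact_radius_um[2]))

  gain <- exp(stats::rnorm(1L, 0, config$staining_gain_sd))
  inten <- config$intensities
  neuronal <- matrix(inten$background, h, w)
  nuclear <- matrix(inten$background, h, w)
  nx <- neurons$x; ny <- neurons$y; nr <- neurons$soma_radius_um
  v_neuron <- min(1, inten$neuron * gain)
  v_nucleus <- min(1, inten$nucleus * gain)
  for (i in seq_along(nx)) {
    neuronal[.disc_pixels(nx[i], ny[i], nr[i], s, h, w)] <- v_neuron
    nuclear[.disc_pixels(nx[i], ny[i], 0.6 * nr[i], s, h, w)] <- v_nucleus
  }
  ax <- artifacts$x; ay <- artifacts$y; ar <- artifacts$radius_um
  v_artifact <- max(min(1, inten$artifact * gain), v_neuron)
  for (i in seq_along(ax)) {
    neuronal[.disc_pixels(ax[i], ay[i], ar[i], s, h, w)] <- v_artifact
  }
  if (config$psf_sigma_px > 0) {
    neuronal <- as.matrix(EBImage::gblur(neuronal, config$psf_sigma_px))
    nuclear <- as.matrix(EBImage::gblur(nuclear, config$psf_sigma_px))
  }
  if (config$noise_sd > 0) {
    neuronal <- neuronal + stats::rnorm(h * w, 0, config$noise_sd)
    nuclear <- nuclear + stats::rnorm(h * w, 0, config$noise_sd)
  }
  neuronal <- matrix(pmin(1, pmax(0, neuronal)), h, w)
  nuclear <- matrix(pmin(1, pmax(0, nuclear)), h, w)

  image <- structure(list(neuronal = neuronal, nuclear = nuclear,
                          pixel_size_um = s, section_id = section_id,
                          condition = condition, distance_mm = distance_mm,
                          gain = gain),
                     class = "section_image")
  truth <- structure(list(neurons = neurons, artifacts = artifacts,
                          section_id = section_id, condition = condition,
                          distance_mm = distance_mm, seed = seed),
                     class = "ground_truth")
  list(image = image, truth = truth)
}

#' @export
print.section_image <- function(x, ...) {
  cat(sprintf("section_image '%s': %d x %d px @ %g um/px, condition=%s, distance=%s mm\n",
              x$section_id, nrow(x$neuronal), ncol(x$neuronal),
              x$pixel_size_um, x$condition,
              if (is.null(x$distance_mm)) "NA" else format(x$distance_mm)))
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth '%s': %d neurons, %d artifacts\n",
              x$section_id, nrow(x$neurons), nrow(x$artifacts)))
  invisible(x)
}

#' Per-region truth counts
#'
#' @param truth a `ground_truth`.
#' @param atlas a `toy_atlas` (defines region order).
#' @return Named integer vector of true neuron counts per region.
#' @export
truth_region_counts <- function(truth, atlas) {
  ids <- atlas$region_info$region_id
  tab <- table(factor(truth$neurons$region_id, levels = ids))
  stats::setNames(as.integer(tab), ids)
}

#' Simulate a pixel-probability map for a section
#'
#' Emulates the output of a pixel-classifier: probability near 1 inside
#' true somas, near 0 on background and artifacts. `miscalibration` is the
#' sd of truncated Gaussian perturbations applied on both sides; 0 yields
#' the exact binary truth map.
#'
#' @param truth a `ground_truth`.
#' @param image the matching `section_image` (supplies raster geometry).
#' @param miscalibration sd >= 0 of the probability perturbation.
#' @param seed RNG seed for the perturbation (default derived from the
#'   truth's seed).
#' @return Matrix of probabilities in \[0, 1\], same dimensions as the
#'   image channels.
#' @export
simulate_probability_map <- function(truth, image, miscalibration = 0,
                                     seed = NULL) {
  stopifnot(miscalibration >= 0)
  dim_hw <- dim(image$neuronal)
  target <- .truth_disc_mask(truth, dim_hw, image$pixel_size_um)
  p <- matrix(as.numeric(target), dim_hw[1], dim_hw[2])
  if (miscalibration > 0) {
    if (is.null(seed)) seed <- .child_seed(truth$seed %||% 0L, 11L)
    set.seed(seed)
    dev <- abs(stats::rnorm(length(p), 0, miscalibration))
    p[target] <- pmax(0, 1 - dev[target])     # neuron pixels drawn near 1
    p[!target] <- pmin(1, dev[!target])       # background/artifacts near 0
  }
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Observer profile
#'
#' @param sensitivity detection probability per true neuron, in \[0, 1\].
#' @param fp_rate false positives per mm² of grey matter.
#' @param jitter_sd_um isotropic localization noise sd (µm).
#' @param seed integer seed.
#' @return An `observer_profile` list.
#' @export
observer_profile <- function(sensitivity = 0.8, fp_rate = 1,
                             jitter_sd_um = 2, seed = 1L) {
  if (sensitivity < 0 || sensitivity > 1) stop("sensitivity must be in [0, 1]")
  if (fp_rate < 0 || jitter_sd_um < 0) stop("fp_rate and jitter_sd_um must be >= 0")
  structure(list(sensitivity = sensitivity, fp_rate = fp_rate,
                 jitter_sd_um = jitter_sd_um, seed = as.integer(seed)),
            class = "observer_profile")
}

#' Simulate one observer's manual annotation of a section
#'
#' Each true neuron is detected independently with probability
#' `sensitivity`; detected positions are jittered by isotropic Gaussian
#' noise; false positives are placed uniformly inside the grey outline at
#' `fp_rate` per mm².
#'
#' @param truth a `ground_truth`.
#' @param atlas the `toy_atlas` (supplies the grey outline).
#' @param profile an `observer_profile`.
#' @param source_id label for the resulting annotation source.
#' @return A `detection_set`.
#' @export
simulate_observer <- function(truth, atlas, profile, source_id = "observer") {
  set.seed(profile$seed)
  n <- nrow(truth$neurons)
  hit <- if (n > 0) stats::runif(n) < profile$sensitivity else logical(0)
  x <- truth$neurons$x[hit]; y <- truth$neurons$y[hit]
  if (profile$jitter_sd_um > 0 && length(x)) {
    x <- x + stats::rnorm(length(x), 0, profile$jitter_sd_um)
    y <- y + stats::rnorm(length(y), 0, profile$jitter_sd_um)
  }
  grey_mm2 <- polygon_area(atlas$grey_outline) / 1e6
  n_fp <- stats::rpois(1L, profile$fp_rate * grey_mm2)
  fp <- .sample_points_in_polygon(n_fp, atlas$grey_outline)
  detection_set(x = c(x, fp[, 1]), y = c(y, fp[, 2]),
                source_id = source_id, section_id = truth$section_id)
}
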