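#' Default wavelength grid of the emulated field imaging spectrometer
#'
#' 344 band centers spanning 379-870 nm with a mean sampling interval of
#' about 1.4 nm. The dispersion is mildly nonuniform, as on the real
#' instrument: 24 bands cover the low-signal region below 410 nm and the
#' remaining 320 cover 410-870 nm, so that discarding wavelengths shorter
#' than 410 nm retains exactly 320 bands and 4-band averaging then yields
#' 80.
#'
#' @param n_bands Total number of bands (default 344).
#' @param range Spectral range in nm (default `c(379, 870)`).
#' @param split Boundary between the two dispersion segments, nm.
#' @param n_below Number of bands strictly below `split`.
#' @return Strictly increasing numeric vector of band centers in nm.
#' @export
fiss_wavelengths <- function(n_bands = 344L, range = c(379, 870),
                             split = 410, n_below = 24L) {
  if (n_below >= n_bands || split <= range[1] || split >= range[2])
    stop("inconsistent wavelength grid parameters", call. = FALSE)
  low <- seq(range[1], split, length.out = n_below + 1L)[seq_len(n_below)]
  high <- seq(split, range[2], length.out = n_bands - n_below)
  c(low, high)
}

#' Synthetic-scene configuration
#'
#' Bundles every parameter of the synthetic field scene: the wavelength
#' grid, per-class reflectance templates (pigment absorption wells, logistic
#' red edge, NIR plateau), the soil ramp, the per-acquisition multiplicative
#' illumination model, sensor noise and quantization, areal cover fractions
#' and image size. The defaults emulate a carrot field infested with
#' purslane, goosegrass and humifuse under varying cloud cover; purslane
#' and goosegrass templates are deliberately the most similar pair.
#'
#' @param n_bands Number of spectral bands (default 344).
#' @param wavelength_range Spectral range in nm (default `c(379, 870)`).
#' @param classes Named list of plant template parameter lists; see
#'   [make_class_templates()] for the parameter meanings.
#' @param soil_template Linear-ramp soil reflectance: `intercept` at the
#'   first wavelength and `slope` per nm.
#' @param illumination List with `sdlog` (log-normal sigma of the
#'   per-acquisition scalar), `shape_slope` (relative tilt of the fixed
#'   smooth spectral shape across the range) and optional `fixed_scale`
#'   overriding the random scalar.
#' @param within_class_sd Per-pixel biological variability: standard
#'   deviations of the Gaussian perturbations applied to each plant
#'   pixel's template parameters (`red_edge_nm` in nm, `red_edge_slope`
#'   in nm, `nir_plateau` and `vis_base` in reflectance units). Zero all
#'   four for pixel-exact class templates.
#' @param noise_sd Additive Gaussian sensor noise standard deviation, DN.
#' @param gain Radiometric gain mapping reflectance to DN (counts per unit
#'   reflectance at unit illumination).
#' @param plant_cover_fraction Named numeric of per-class areal fractions;
#'   the remainder is soil.
#' @param image_size `c(rows, cols)` of generated scenes.
#' @param patch_px Side length in pixels of the square vegetation patches
#'   used to lay out the label image.
#' @param bit_depth Sensor quantization depth (default 12).
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(n_bands = 344L,
                         wavelength_range = c(379, 870),
                         classes = default_class_params(),
                         soil_template = list(intercept = 0.08,
                                              slope = 0.00025),
                         illumination = list(sdlog = 0.25,
                                             shape_slope = 0.15,
                                             fixed_scale = NULL),
                         within_class_sd = list(red_edge_nm = 2.5,
                                                red_edge_slope = 1.0,
                                                nir_plateau = 0.03,
                                                vis_base = 0.008),
                         noise_sd = 3,
                         gain = 3200,
                         plant_cover_fraction = c(carrot = 0.15,
                                                  purslane = 0.10,
                                                  goosegrass = 0.10,
                                                  humifuse = 0.10),
                         image_size = c(48L, 48L),
                         patch_px = 8L,
                         bit_depth = 12L) {
  if (!setequal(names(classes), names(plant_cover_fraction)))
    stop("`classes` and `plant_cover_fraction` must name the same classes",
         call. = FALSE)
  if (sum(plant_cover_fraction) >= 1 || any(plant_cover_fraction <= 0))
    stop("plant cover fractions must be positive and sum to < 1 ",
         "(the remainder is soil)", call. = FALSE)
  cfg <- structure(
    list(n_bands = as.integer(n_bands),
         wavelength_range = wavelength_range,
         wavelengths = if (n_bands == 344L &&
                           identical(wavelength_range, c(379, 870)))
           fiss_wavelengths()
         else seq(wavelength_range[1], wavelength_range[2],
                  length.out = n_bands),
         classes = classes, soil_template = soil_template,
         illumination = illumination, within_class_sd = within_class_sd,
         noise_sd = noise_sd, gain = gain,
         plant_cover_fraction = plant_cover_fraction,
         image_size = as.integer(image_size), patch_px = as.integer(patch_px),
         bit_depth = as.integer(bit_depth)),
    class = "scene_config")
  tpl <- make_class_templates(cfg)   # validates template range
  cfg
}

#' Default plant reflectance template parameters
#'
#' Each template has: `vis_base` visible baseline reflectance; `green_peak`
#' green-bump amplitude at 550 nm; `abs_blue`/`abs_red` chlorophyll
#' absorption-well depths centered at 450/660 nm; `red_edge_nm` logistic
#' red-edge inflection; `red_edge_slope` logistic scale in nm;
#' `nir_plateau` NIR reflectance. Purslane and goosegrass are the most
#' similar pair (hardest to separate); humifuse and carrot are distinct.
#'
#' @return Named list of per-class parameter lists.
#' @export
default_class_params <- function() {
  list(
    carrot     = list(vis_base = 0.10, green_peak = 0.050, abs_blue = 0.060,
                      abs_red = 0.070, red_edge_nm = 712, red_edge_slope = 9,
                      nir_plateau = 0.48),
    purslane   = list(vis_base = 0.09, green_peak = 0.040, abs_blue = 0.050,
                      abs_red = 0.060, red_edge_nm = 719, red_edge_slope = 11,
                      nir_plateau = 0.42),
    goosegrass = list(vis_base = 0.09, green_peak = 0.045, abs_blue = 0.050,
                      abs_red = 0.060, red_edge_nm = 722, red_edge_slope = 13,
                      nir_plateau = 0.44),
    humifuse   = list(vis_base = 0.12, green_peak = 0.070, abs_blue = 0.070,
                      abs_red = 0.080, red_edge_nm = 705, red_edge_slope = 7,
                      nir_plateau = 0.55))
}

plant_reflectance <- function(wl, p) {
  vis <- p$vis_base +
    p$green_peak * exp(-0.5 * ((wl - 550) / 25)^2) -
    p$abs_blue   * exp(-0.5 * ((wl - 450) / 30)^2) -
    p$abs_red    * exp(-0.5 * ((wl - 660) / 25)^2)
  edge <- stats::plogis((wl - p$red_edge_nm) / p$red_edge_slope)
  vis * (1 - edge) + p$nir_plateau * edge
}

#' Per-class reflectance templates on the configured wavelength grid
#'
#' Plant curves have low visible reflectance with pigment absorption wells
#' at 450 and 660 nm, a monotone logistic rise through the red-edge window
#' and a flat NIR plateau; soil is a smooth monotone ramp. All curves are
#' validated to lie in `[0, 1]`.
#'
#' @param config A [scene_config()].
#' @return Numeric matrix `n_bands x (n_classes + 1)`; the last column is
#'   `"soil"`.
#' @export
make_class_templates <- function(config) {
  stopifnot(inherits(config, "scene_config") || is.list(config))
  wl <- config$wavelengths
  tpl <- vapply(config$classes, function(p) plant_reflectance(wl, p),
                numeric(length(wl)))
  soil <- config$soil_template$intercept +
    config$soil_template$slope * (wl - wl[1L])
  tpl <- cbind(tpl, soil = soil)
  if (any(tpl < 0) || any(tpl > 1))
    stop("config error: reflectance templates leave [0, 1]", call. = FALSE)
  rownames(tpl) <- NULL
  tpl
}

illumination_shape <- function(config) {
  wl <- config$wavelengths
  1 + config$illumination$shape_slope *
    (wl - wl[1L]) / (wl[length(wl)] - wl[1L])
}

#' Generate one synthetic scene
#'
#' Lays out square vegetation patches on a soil background (every
#' configured class is guaranteed present), draws one multiplicative
#' illumination scalar for the acquisition (log-normal, emulating varying
#' cloud cover), and renders each pixel as
#' `DN = round(clip(scale * shape(lambda) * reflectance(lambda) * gain
#' + noise))` within the sensor's quantization range. Deterministic given
#' `seed`.
#'
#' @param config A [scene_config()].
#' @param seed Integer RNG seed.
#' @param acquisition_id Identifier stored in the cube.
#' @param quantize If `FALSE`, skip rounding/clipping (useful for verifying
#'   the multiplicative illumination model exactly).
#' @return List with elements `cube` (a [spectral_cube()]) and `truth`
#'   (list with `labels`, a rows-x-cols character matrix with `"soil"` for
#'   background, and `illumination_scale`).
#' @export
generate_scene <- function(config, seed, acquisition_id = "img001",
                           quantize = TRUE) {
  stopifnot(inherits(config, "scene_config"))
  set.seed(seed)
  nr <- config$image_size[1L]; nc <- config$image_size[2L]
  cls <- names(config$classes)
  frac <- config$plant_cover_fraction

  # label layout: patch grid; first |classes| patches forced one per class
  pr <- ceiling(nr / config$patch_px); pc <- ceiling(nc / config$patch_px)
  n_patch <- pr * pc
  if (n_patch < length(cls))
    stop("image too small to host every class", call. = FALSE)
  patch_lab <- sample(c(cls, "soil"), n_patch, replace = TRUE,
                      prob = c(frac, 1 - sum(frac)))
  forced <- sample.int(n_patch, length(cls))
  patch_lab[forced] <- sample(cls)
  labels <- matrix("soil", nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    p <- ((i - 1L) %/% config$patch_px) * pc + ((j - 1L) %/% config$patch_px) + 1L
    labels[i, j] <- patch_lab[p]
  }

  s <- config$illumination$fixed_scale
  if (is.null(s)) s <- stats::rlnorm(1L, 0, config$illumination$sdlog)
  shape <- illumination_shape(config)
  tpl <- make_class_templates(config)

  nb <- config$n_bands
  dn <- matrix(0, nb, nr * nc)
  lab_vec <- as.vector(labels)          # column-major pixel order
  wcs <- config$within_class_sd
  jitter_on <- !is.null(wcs) && any(unlist(wcs) > 0)
  wl <- config$wavelengths
  for (k in colnames(tpl)) {
    pix <- which(lab_vec == k)
    if (!length(pix)) next
    if (k == "soil" || !jitter_on) {
      dn[, pix] <- s * shape * tpl[, k] * config$gain
    } else {
      # per-pixel biological variability around the class template
      p0 <- config$classes[[k]]
      for (px in pix) {
        p <- p0
        p$red_edge_nm <- p0$red_edge_nm + stats::rnorm(1, 0, wcs$red_edge_nm)
        p$red_edge_slope <- max(1, p0$red_edge_slope +
                                  stats::rnorm(1, 0, wcs$red_edge_slope))
        p$nir_plateau <- p0$nir_plateau + stats::rnorm(1, 0, wcs$nir_plateau)
        p$vis_base <- p0$vis_base + stats::rnorm(1, 0, wcs$vis_base)
        refl <- pmin(1, pmax(0, plant_reflectance(wl, p)))
        dn[, px] <- s * shape * refl * config$gain
      }
    }
  }
  if (config$noise_sd > 0)
    dn <- dn + stats::rnorm(length(dn), sd = config$noise_sd)
  if (quantize) {
    dn <- round(dn)
    dn[dn < 0] <- 0
    dn_max <- 2^config$bit_depth - 1
    dn[dn > dn_max] <- dn_max
  }
  cube <- spectral_cube(array(dn, dim = c(nb, nr, nc)), config$wavelengths,
                        bit_depth = config$bit_depth,
                        acquisition_id = acquisition_id)
  list(cube = cube,
       truth = list(labels = labels, illumination_scale = s))
}

#' Generate a series of acquisitions with independent illumination
#'
#' Each image draws its own illumination scalar (emulating cloud-cover
#' drift between acquisitions) and carries a distinct acquisition id.
#'
#' @param config A [scene_config()].
#' @param n_images Number of images (the emulated field campaign used 41).
#' @param seed Integer RNG seed; per-image sub-seeds are derived from it.
#' @return List of `list(cube, truth)` elements, length `n_images`.
#' @export
generate_acquisition_series <- function(config, n_images, seed) {
  if (n_images < 1L) stop("`n_images` must be >= 1", call. = FALSE)
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max - 1L, n_images)
  lapply(seq_len(n_images), function(i)
    generate_scene(config, seed = sub[i],
                   acquisition_id = sprintf("img%03d", i)))
}

#' Sample labelled plant pixels from disjoint image sets
#'
#' Draws exactly `n_per_class` pixels per plant class per role, uniformly
#' without replacement, from the designated acquisitions only. Train and
#' validation image sets must be disjoint, preserving the independence of
#' the two sample tables.
#'
#' @param series Output of [generate_acquisition_series()].
#' @param n_per_class Pixels per class per role (the emulated design uses
#'   3000).
#' @param train_images,validation_images Disjoint character vectors of
#'   acquisition ids.
#' @param seed Integer RNG seed.
#' @param classes Plant classes to sample; defaults to every non-soil class
#'   in the first image's ground truth (sorted for determinism).
#' @return List with `train` and `validation`, each a [labeled_samples()]
#'   of raw-band spectra (`n_per_class * n_classes` rows).
#' @export
sample_pixels <- function(series, n_per_class, train_images,
                          validation_images, seed,
                          classes = NULL) {
  if (length(intersect(train_images, validation_images)))
    stop("train and validation image sets must be disjoint", call. = FALSE)
  set.seed(seed)
  ids <- vapply(series, function(s) s$cube$acquisition_id, character(1))
  cls <- classes %||%
    sort(setdiff(unique(c(series[[1L]]$truth$labels)), "soil"))
  wl <- series[[1L]]$cube$wavelengths

  draw_role <- function(image_set, role) {
    take <- series[match(image_set, ids)]
    if (anyNA(match(image_set, ids)))
      stop("unknown acquisition id in image set", call. = FALSE)
    spectra <- vector("list", length(cls))
    labs <- img <- vector("list", length(cls))
    for (ci in seq_along(cls)) {
      k <- cls[ci]
      pool_spec <- list(); pool_img <- character(0)
      for (s in take) {
        m <- s$truth$labels == k
        if (any(m)) {
          px <- extract_pixels(s$cube, m)
          pool_spec[[length(pool_spec) + 1L]] <- px
          pool_img <- c(pool_img, rep(s$cube$acquisition_id, nrow(px)))
        }
      }
      if (!length(pool_spec))
        stop("sampling error: class '", k, "' absent from the ", role,
             " images", call. = FALSE)
      pool <- do.call(rbind, pool_spec)
      if (nrow(pool) < n_per_class)
        stop("sampling error: class '", k, "' has only ", nrow(pool),
             " pixels in the ", role, " images (need ", n_per_class, ")",
             call. = FALSE)
      pick <- sample.int(nrow(pool), n_per_class)
      spectra[[ci]] <- pool[pick, , drop = FALSE]
      labs[[ci]] <- rep(k, n_per_class)
      img[[ci]] <- pool_img[pick]
    }
    labeled_samples(do.call(rbind, spectra), unlist(labs), unlist(img),
                    feature_wavelengths = wl, role = role,
                    class_set = cls)
  }
  list(train = draw_role(train_images, "train"),
       validation = draw_role(validation_images, "validation"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
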