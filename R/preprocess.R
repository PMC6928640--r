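# The preprocessing chain, in the order the pipeline fixes it:
# trim_bands -> average_bands -> normalize, then NDVI/Otsu soil masking on
# the averaged data.

#' Discard low-signal short-wavelength bands
#'
#' Bands with center wavelength below `min_wavelength_nm` (default 410 nm,
#' where the sensor's signal-to-noise ratio collapses) are dropped; band
#' order is preserved. Works on a [spectral_cube()] or on
#' [labeled_samples()] whose features are spectral bands.
#'
#' @param x A `spectral_cube` or `labeled_samples`.
#' @param min_wavelength_nm Retain bands with wavelength >= this value.
#' @return Object of the same class with the trimmed band set.
#' @export
trim_bands <- function(x, min_wavelength_nm = 410) {
  UseMethod("trim_bands")
}

trim_keep <- function(wl, min_wavelength_nm) {
  keep <- which(wl >= min_wavelength_nm)
  if (!length(keep))
    stop("trim threshold removes every band", call. = FALSE)
  keep
}

#' @export
trim_bands.spectral_cube <- function(x, min_wavelength_nm = 410) {
  keep <- trim_keep(x$wavelengths, min_wavelength_nm)
  spectral_cube(x$dn[keep, , , drop = FALSE], x$wavelengths[keep],
                x$bit_depth, x$platform_height_mm, x$acquisition_id)
}

#' @export
trim_bands.labeled_samples <- function(x, min_wavelength_nm = 410) {
  if (is.null(x$feature_wavelengths))
    stop("samples carry no wavelength table; features are not bands",
         call. = FALSE)
  keep <- trim_keep(x$feature_wavelengths, min_wavelength_nm)
  labeled_samples(x$spectra[, keep, drop = FALSE], x$labels, x$image_ids,
                  feature_wavelengths = x$feature_wavelengths[keep],
                  role = x$role, class_set = x$class_set)
}

#' Average adjacent bands in fixed blocks
#'
#' Reduces dimension and noise by replacing every block of `block` adjacent
#' bands with their unweighted mean; the output band center is the mean of
#' the block's centers. 320 retained bands with the default block of 4
#' yield 80 bands. A trailing remainder that does not fill a block is
#' dropped with a warning.
#'
#' @param x A `spectral_cube` or `labeled_samples` (band features).
#' @param block Block size, a positive integer (default 4).
#' @return Object of the same class with `floor(n_bands / block)` bands.
#' @export
average_bands <- function(x, block = 4L) {
  UseMethod("average_bands")
}

block_groups <- function(n, block) {
  block <- as.integer(block)
  if (is.na(block) || block < 1L) stop("`block` must be >= 1", call. = FALSE)
  n_out <- n %/% block
  if (n_out < 1L) stop("fewer bands than one block", call. = FALSE)
  if (n %% block != 0L)
    warning(sprintf("dropping %d trailing band(s) not filling a block",
                    n %% block), call. = FALSE)
  split(seq_len(n_out * block), rep(seq_len(n_out), each = block))
}

#' @export
average_bands.spectral_cube <- function(x, block = 4L) {
  g <- block_groups(dim(x$dn)[1L], block)
  nb <- length(g)
  d <- dim(x$dn)
  flat <- matrix(x$dn, nrow = d[1L])
  out <- matrix(0, nb, ncol(flat))
  for (j in seq_len(nb)) out[j, ] <- colMeans(flat[g[[j]], , drop = FALSE])
  wl <- vapply(g, function(i) mean(x$wavelengths[i]), numeric(1))
  spectral_cube(array(out, dim = c(nb, d[2L], d[3L])), unname(wl),
                x$bit_depth, x$platform_height_mm, x$acquisition_id)
}

#' @export
average_bands.labeled_samples <- function(x, block = 4L) {
  if (is.null(x$feature_wavelengths))
    stop("samples carry no wavelength table; features are not bands",
         call. = FALSE)
  g <- block_groups(ncol(x$spectra), block)
  out <- vapply(g, function(i) rowMeans(x$spectra[, i, drop = FALSE]),
                numeric(nrow(x$spectra)))
  if (nrow(x$spectra) == 1L) out <- matrix(out, nrow = 1L)
  wl <- vapply(g, function(i) mean(x$feature_wavelengths[i]), numeric(1))
  labeled_samples(out, x$labels, x$image_ids,
                  feature_wavelengths = unname(wl),
                  role = x$role, class_set = x$class_set)
}

#' Mean-normalize a pixel spectrum
#'
#' Divides each band by the spectrum's arithmetic mean, so the normalized
#' spectrum has mean exactly 1. Because a change in illumination under the
#' acquisition model is a common multiplicative scalar across bands, this
#' normalization removes it: `normalize_spectrum(c * x)` equals
#' `normalize_spectrum(x)` for any `c > 0`, and the operation is
#' idempotent.
#'
#' @param spectrum Numeric vector of band values with positive mean.
#' @return Numeric vector of the same length with mean 1.
#' @export
normalize_spectrum <- function(spectrum) {
  m <- mean(spectrum)
  if (!is.finite(m) || m <= 0)
    stop("spectrum mean must be positive (dead or masked pixel?)",
         call. = FALSE)
  spectrum / m
}

#' Mean-normalize every row of a sample table
#'
#' Applies [normalize_spectrum()] to each sample's spectrum.
#'
#' @param samples A [labeled_samples()].
#' @return A [labeled_samples()] whose rows each have mean 1.
#' @export
normalize_samples <- function(samples) {
  stopifnot(inherits(samples, "labeled_samples"))
  m <- rowMeans(samples$spectra)
  if (any(!is.finite(m)) || any(m <= 0))
    stop("every sample spectrum must have positive mean", call. = FALSE)
  labeled_samples(samples$spectra / m, samples$labels, samples$image_ids,
                  feature_wavelengths = samples$feature_wavelengths,
                  role = samples$role, class_set = samples$class_set)
}

#' Compute an NDVI map from a cube
#'
#' NDVI = (DN_NIR - DN_R) / (DN_NIR + DN_R), using the bands whose centers
#' are nearest the requested near-infrared (default 760 nm) and red
#' (default 660 nm) wavelengths (ties to the lower wavelength). Pixels
#' with a zero denominator are assigned NDVI 0 and flagged; they are never
#' counted as vegetation.
#'
#' @param cube A [spectral_cube()], typically after trimming/averaging.
#' @param nir_nm,red_nm Target band-center wavelengths in nm.
#' @return An object of class `ndvi_map`: fields `ndvi` (rows x cols
#'   matrix in `[-1, 1]`), `nir_wavelength_nm`, `red_wavelength_nm` (the
#'   band centers actually used), `zero_flag` (logical matrix), and unset
#'   `threshold`/`mask` until [threshold_plants()] is applied.
#' @export
compute_ndvi <- function(cube, nir_nm = 760, red_nm = 660) {
  stopifnot(inherits(cube, "spectral_cube"))
  wl <- cube$wavelengths
  rng <- range(wl)
  if (nir_nm < rng[1] || nir_nm > rng[2] || red_nm < rng[1] ||
      red_nm > rng[2])
    stop("requested NDVI wavelength outside the cube's spectral range",
         call. = FALSE)
  nearest <- function(target) {
    d <- abs(wl - target)
    which(d == min(d))[1L]          # ties -> lower wavelength
  }
  bn <- nearest(nir_nm); br <- nearest(red_nm)
  nir <- cube$dn[bn, , ]; red <- cube$dn[br, , ]
  den <- nir + red
  zero <- den == 0
  ndvi <- matrix(0, nrow(den), ncol(den))
  ndvi[!zero] <- (nir[!zero] - red[!zero]) / den[!zero]
  structure(list(ndvi = ndvi, nir_wavelength_nm = wl[bn],
                 red_wavelength_nm = wl[br], zero_flag = zero,
                 threshold = NULL, mask = NULL),
            class = "ndvi_map")
}

#' Otsu threshold of a value vector
#'
#' Maximizes the between-class variance of the two groups induced by a
#' histogram threshold (256 bins over the given range); the threshold
#' returned is the upper edge of the chosen bin, so `value > threshold`
#' selects the upper mode. Deterministic; first maximum wins on ties.
#'
#' @param values Numeric vector.
#' @param n_bins Number of histogram bins (default 256).
#' @param range Histogram support (default `c(-1, 1)`, the NDVI range).
#' @return The threshold value.
#' @export
otsu_threshold <- function(values, n_bins = 256L, range = c(-1, 1)) {
  if (length(unique(values)) < 2L)
    stop("degenerate single-valued histogram; supply a manual threshold",
         call. = FALSE)
  edges <- seq(range[1], range[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(values, edges, rightmost.closed = TRUE,
                             all.inside = TRUE), nbins = n_bins)
  p <- h / sum(h)
  centers <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  omega <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_t <- mu[n_bins]
  valid <- omega > 0 & omega < 1
  sigma_b <- rep(-Inf, n_bins)
  sigma_b[valid] <- (mu_t * omega[valid] - mu[valid])^2 /
    (omega[valid] * (1 - omega[valid]))
  k <- which.max(sigma_b)
  edges[k + 1L]
}

#' Segment plant pixels by NDVI thresholding
#'
#' Chooses the soil/plant threshold by Otsu's between-class-variance
#' maximization on the NDVI histogram (256 bins over `[-1, 1]`), or uses a
#' manual override; the plant mask is `ndvi > threshold`, with
#' zero-denominator pixels always excluded.
#'
#' @param ndvi_map An [compute_ndvi()] result.
#' @param threshold Optional manual threshold overriding Otsu.
#' @return The `ndvi_map` with `threshold` and `mask` set.
#' @export
threshold_plants <- function(ndvi_map, threshold = NULL) {
  stopifnot(inherits(ndvi_map, "ndvi_map"))
  if (is.null(threshold))
    threshold <- otsu_threshold(as.vector(ndvi_map$ndvi))
  ndvi_map$threshold <- threshold
  ndvi_map$mask <- ndvi_map$ndvi > threshold & !ndvi_map$zero_flag
  ndvi_map
}

#' Record preprocessing parameters as a JSON provenance sidecar
#'
#' @param path Output JSON path.
#' @param trim_nm,block Trim threshold (nm) and averaging block size.
#' @param ndvi_map Optional thresholded [compute_ndvi()] result whose band
#'   centers and threshold are recorded.
#' @return `path`, invisibly.
#' @export
write_preprocess_sidecar <- function(path, trim_nm = 410, block = 4L,
                                     ndvi_map = NULL) {
  rec <- list(trim_min_wavelength_nm = trim_nm, average_block = block)
  if (!is.null(ndvi_map))
    rec <- c(rec, list(ndvi_nir_nm = ndvi_map$nir_wavelength_nm,
                       ndvi_red_nm = ndvi_map$red_wavelength_nm,
                       ndvi_threshold = ndvi_map$threshold))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
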