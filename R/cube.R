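#' Construct a spectral cube
#'
#' A `spectral_cube` holds raw digital numbers (DN) from a line-scanning
#' imaging spectrometer as a 3-D array indexed `[band, row, col]`, together
#' with the band-center wavelength table and acquisition metadata.
#'
#' @param dn 3-D numeric array of digital numbers, dimensions
#'   `(band, row, col)`. Values must lie in `[0, 2^bit_depth - 1]`.
#' @param wavelengths Numeric vector of band-center wavelengths in nm,
#'   strictly increasing, one per band.
#' @param bit_depth Integer quantization depth of the sensor (default 12).
#' @param platform_height_mm Height of the scanning platform above the
#'   canopy in mm; determines ground resolution via [ground_resolution()].
#' @param acquisition_id Character token identifying the acquisition.
#'
#' @return An object of class `spectral_cube`.
#' @export
spectral_cube <- function(dn, wavelengths, bit_depth = 12L,
                          platform_height_mm = 1000,
                          acquisition_id = "img001") {
  if (!is.array(dn) || length(dim(dn)) != 3L)
    stop("`dn` must be a 3-D array (band, row, col)", call. = FALSE)
  if (length(wavelengths) != dim(dn)[1L])
    stop("length(wavelengths) must equal the band dimension of `dn`",
         call. = FALSE)
  if (any(diff(wavelengths) <= 0))
    stop("`wavelengths` must be strictly increasing", call. = FALSE)
  dn_max <- 2^bit_depth - 1
  if (any(dn < 0) || any(dn > dn_max))
    stop(sprintf("DN values must lie in [0, %d]", dn_max), call. = FALSE)
  structure(
    list(dn = dn, wavelengths = as.numeric(wavelengths),
         bit_depth = as.integer(bit_depth),
         platform_height_mm = platform_height_mm,
         acquisition_id = acquisition_id),
    class = "spectral_cube")
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$dn)
  cat(sprintf(
    "<spectral_cube '%s'> %d bands x %d rows x %d cols, %.0f-%.0f nm, %d-bit\n",
    x$acquisition_id, d[1], d[2], d[3],
    min(x$wavelengths), max(x$wavelengths), x$bit_depth))
  invisible(x)
}

#' Ground resolution of the scanning platform
#'
#' The instrument's ground sampling distance scales linearly with platform
#' height: `r = 0.001 * h`, with `h` in mm giving `r` in mm/pixel. At the
#' nominal 1 m operating height this is 1 mm/pixel.
#'
#' @param platform_height_mm Platform height in mm, positive.
#' @return Ground resolution in mm/pixel.
#' @export
ground_resolution <- function(platform_height_mm) {
  if (!is.numeric(platform_height_mm) || any(platform_height_mm <= 0))
    stop("`platform_height_mm` must be positive", call. = FALSE)
  0.001 * platform_height_mm
}

#' Extract pixel spectra under a mask
#'
#' Pulls the spectra of all mask-true pixels out of a cube, one row per
#' pixel, in row-major spatial order (origin top-left, row index varying
#' slowest within a row, i.e. pixels read left-to-right, top-to-bottom).
#'
#' @param cube A [spectral_cube()].
#' @param mask Logical matrix with the cube's spatial dimensions
#'   (`rows x cols`); `TRUE` marks pixels to extract.
#' @return Numeric matrix `n_pixels x n_bands`; zero rows for an all-false
#'   mask. Band order is preserved exactly.
#' @export
extract_pixels <- function(cube, mask) {
  stopifnot(inherits(cube, "spectral_cube"))
  d <- dim(cube$dn)
  if (!is.logical(mask) || !identical(dim(mask), d[2:3]))
    stop("`mask` must be a logical matrix matching the cube's spatial dims",
         call. = FALSE)
  hits <- which(mask, arr.ind = TRUE)
  out <- matrix(numeric(0), nrow = 0L, ncol = d[1L])
  if (nrow(hits) > 0L) {
    ord <- order(hits[, 1L], hits[, 2L])  # row-major
    hits <- hits[ord, , drop = FALSE]
    flat <- matrix(cube$dn, nrow = d[1L])  # pixel cols in column-major order
    pix <- (hits[, 2L] - 1L) * d[2L] + hits[, 1L]
    out <- t(flat[, pix, drop = FALSE])
  }
  colnames(out) <- sprintf("b%03d", seq_len(d[1L]))
  out
}

#' Construct a labelled pixel-sample table
#'
#' Holds a matrix of pixel spectra (raw bands, preprocessed bands, or
#' wavelet coefficients) with per-row class labels and source-acquisition
#' ids, plus the role of the table in the experiment design.
#'
#' @param spectra Numeric matrix `n_samples x n_features`.
#' @param labels Character/factor vector of class labels, one per row.
#' @param image_ids Character vector of source acquisition ids, one per row.
#' @param feature_wavelengths Numeric vector of band-center wavelengths in
#'   nm, or `NULL` when the features are not spectral bands (e.g. wavelet
#'   coefficients).
#' @param role `"train"` or `"validation"`.
#' @param class_set Allowed label values; defaults to the labels present.
#' @return An object of class `labeled_samples`.
#' @export
labeled_samples <- function(spectra, labels, image_ids,
                            feature_wavelengths = NULL,
                            role = c("train", "validation"),
                            class_set = NULL) {
  role <- match.arg(role)
  spectra <- as.matrix(spectra)
  labels <- as.character(labels)
  image_ids <- as.character(image_ids)
  if (nrow(spectra) != length(labels) || nrow(spectra) != length(image_ids))
    stop("rows of `spectra` must match length of `labels` and `image_ids`",
         call. = FALSE)
  if (is.null(class_set)) class_set <- unique(labels)
  if (!all(labels %in% class_set))
    stop("labels outside the declared class set: ",
         paste(setdiff(labels, class_set), collapse = ", "), call. = FALSE)
  if (!is.null(feature_wavelengths) &&
      length(feature_wavelengths) != ncol(spectra))
    stop("`feature_wavelengths` must have one entry per feature column",
         call. = FALSE)
  structure(
    list(spectra = spectra, labels = labels, image_ids = image_ids,
         feature_wavelengths = feature_wavelengths,
         role = role, class_set = class_set),
    class = "labeled_samples")
}

#' @export
print.labeled_samples <- function(x, ...) {
  cat(sprintf("<labeled_samples> %d samples x %d features (%s)\n",
              nrow(x$spectra), ncol(x$spectra), x$role))
  print(table(x$labels))
  invisible(x)
}

#' Write a labelled sample table to CSV
#'
#' Columns: `image_id`, `class`, then one column per feature.
#'
#' @param samples A [labeled_samples()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_samples_csv <- function(samples, path) {
  stopifnot(inherits(samples, "labeled_samples"))
  df <- data.frame(image_id = samples$image_ids, class = samples$labels,
                   samples$spectra, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a labelled sample table from CSV
#'
#' @param path CSV written by [write_samples_csv()].
#' @param role Role to assign, `"train"` or `"validation"`.
#' @param feature_wavelengths Optional wavelength table for the feature
#'   columns.
#' @return A [labeled_samples()].
#' @export
read_samples_csv <- function(path, role = "train",
                             feature_wavelengths = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("image_id", "class") %in% names(df)))
    stop("sample CSV must have `image_id` and `class` columns", call. = FALSE)
  feat <- as.matrix(df[, setdiff(names(df), c("image_id", "class")),
                       drop = FALSE])
  labeled_samples(feat, df$class, df$image_id,
                  feature_wavelengths = feature_wavelengths, role = role)
}
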