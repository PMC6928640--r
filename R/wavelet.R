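# Multilevel 1-D discrete wavelet transform with the Daubechies-3 (db3)
# filter pair, half-point symmetric boundary extension and per-level
# output length floor((n - 1) / 2) + L/2. Under this convention an
# 80-sample spectrum decomposes (auto depth) into detail levels of length
# 42, 23, 14, 9, 7, 6, 5 plus a final approximation of length 5 -- 111
# coefficients in total.

# db3 orthonormal filter bank (L = 6). dec_* are the analysis filters,
# rec_* the synthesis filters; dec_lo is the time-reversed scaling filter.
db3_filters <- function() {
  rec_lo <- c(0.33267055295008263, 0.80689150931109250, 0.45987750211849154,
              -0.13501102001025458, -0.08544127388202666, 0.03522629188570953)
  L <- length(rec_lo)
  rec_hi <- (-1)^(seq_len(L) - 1L) * rev(rec_lo)   # QMF pair
  list(dec_lo = rev(rec_lo), dec_hi = rev(rec_hi),
       rec_lo = rec_lo, rec_hi = rec_hi, L = L)
}

# half-point symmetric extension by L-1 samples each side
sym_extend <- function(x, L) {
  n <- length(x)
  c(x[(L - 1L):1L], x, x[n:(n - L + 2L)])
}

dwt_step <- function(x, f) {
  L <- length(f$dec_lo)
  n <- length(x)
  ext <- sym_extend(x, L)
  K <- (n + L - 1L) %/% 2L                 # = floor((n - 1)/2) + L/2
  idx <- seq(L + 1L, by = 2L, length.out = K)
  ylo <- stats::convolve(ext, rev(f$dec_lo), type = "open")[idx]
  yhi <- stats::convolve(ext, rev(f$dec_hi), type = "open")[idx]
  list(cA = ylo, cD = yhi)
}

idwt_step <- function(cA, cD, f, out_len) {
  if (length(cA) != length(cD))
    stop("inconsistent level lengths in decomposition", call. = FALSE)
  L <- length(f$rec_lo)
  K <- length(cA)
  up <- function(cc) { u <- numeric(2L * K); u[seq(1L, 2L * K, 2L)] <- cc; u }
  s <- stats::convolve(up(cA), rev(f$rec_lo), type = "open") +
       stats::convolve(up(cD), rev(f$rec_hi), type = "open")
  full <- 2L * K - L + 2L
  if (out_len > full || out_len < full - 1L)
    stop("inconsistent level lengths in decomposition", call. = FALSE)
  s[seq(L - 1L, length.out = out_len)]
}

#' Multilevel discrete wavelet transform of a spectrum
#'
#' Pyramid DWT with the db3 filter (length 6) and half-point symmetric
#' boundary extension; each level's output length is
#' `floor((n - 1) / 2) + 3`. With `levels = "auto"` the approximation is
#' decomposed further while its length exceeds `L - 1 = 5`, which takes an
#' 80-band spectrum through detail lengths 42, 23, 14, 9, 7, 6, 5 to a
#' final approximation of length 5 (111 coefficients).
#'
#' @param spectrum Numeric vector, length at least the filter length (6).
#' @param mother Mother wavelet token; only `"db3"` is provided.
#' @param levels `"auto"` or a positive integer decomposition depth.
#' @return An object of class `wavelet_decomposition`: `mother`, `levels`,
#'   `detail_coeffs` (list, element `j` = level-`j` details, level 1
#'   finest), `approx_coeffs`, `level_lengths` (finest first), `energies`
#'   (per-level, as-printed mode: plain mean of coefficients), and
#'   `input_length`.
#' @export
dwt <- function(spectrum, mother = "db3", levels = "auto") {
  if (mother != "db3")
    stop("only the db3 mother wavelet is provided", call. = FALSE)
  f <- db3_filters()
  n0 <- length(spectrum)
  if (n0 < f$L)
    stop("spectrum shorter than the wavelet filter (", f$L, ")",
         call. = FALSE)
  auto <- identical(levels, "auto")
  if (!auto && (!is.numeric(levels) || levels < 1L))
    stop("`levels` must be \"auto\" or a positive integer", call. = FALSE)
  cA <- as.numeric(spectrum)
  details <- list()
  j <- 0L
  repeat {
    if (auto) {
      if (length(cA) <= f$L - 1L) break
    } else if (j >= levels) break
    if (length(cA) < f$L)
      stop("requested depth exceeds what the spectrum length supports",
           call. = FALSE)
    st <- dwt_step(cA, f)
    j <- j + 1L
    details[[j]] <- st$cD
    cA <- st$cA
  }
  structure(
    list(mother = mother, levels = j,
         detail_coeffs = details, approx_coeffs = cA,
         level_lengths = vapply(details, length, integer(1)),
         energies = vapply(details, mean, numeric(1)),
         input_length = n0),
    class = "wavelet_decomposition")
}

#' @export
print.wavelet_decomposition <- function(x, ...) {
  cat(sprintf(
    "<wavelet_decomposition> %s, %d levels; detail lengths %s + approx %d (total %d)\n",
    x$mother, x$levels, paste(rev(x$level_lengths), collapse = ","),
    length(x$approx_coeffs),
    sum(x$level_lengths) + length(x$approx_coeffs)))
  invisible(x)
}

#' Invert a multilevel wavelet decomposition
#'
#' Reconstructs the original spectrum from the pyramid; the round-trip
#' `inverse_dwt(dwt(x))` is exact to floating-point accuracy because the
#' boundary-extended transform is slightly redundant.
#'
#' @param decomp A [dwt()] result.
#' @return Numeric vector of length `decomp$input_length`.
#' @export
inverse_dwt <- function(decomp) {
  stopifnot(inherits(decomp, "wavelet_decomposition"))
  f <- db3_filters()
  lens <- c(decomp$input_length, decomp$level_lengths)
  cA <- decomp$approx_coeffs
  for (j in rev(seq_len(decomp$levels)))
    cA <- idwt_step(cA, decomp$detail_coeffs[[j]], f, out_len = lens[j])
  cA
}

#' Per-level wavelet energy
#'
#' Summarizes the level-`j` coefficients. The `"as_printed"` mode is the
#' plain mean `(1/K) * sum(W(j, k))` (which can be negative and is kept
#' for fidelity with the quantity's published definition); `"squared"` is
#' the conventional mean square `(1/K) * sum(W(j, k)^2)`.
#'
#' @param decomp A [dwt()] result.
#' @param j Detail level, `1 .. levels` (1 = finest), or `"approx"` for
#'   the final approximation.
#' @param mode `"as_printed"` (default) or `"squared"`.
#' @return A single number.
#' @export
level_energy <- function(decomp, j, mode = c("as_printed", "squared")) {
  stopifnot(inherits(decomp, "wavelet_decomposition"))
  mode <- match.arg(mode)
  w <- if (identical(j, "approx")) decomp$approx_coeffs
  else {
    if (!is.numeric(j) || j < 1L || j > decomp$levels)
      stop("level out of range", call. = FALSE)
    decomp$detail_coeffs[[j]]
  }
  if (mode == "as_printed") mean(w) else mean(w^2)
}

#' Replace 80-band spectra with their 111 wavelet coefficients
#'
#' Applies the auto-depth db3 [dwt()] to each row and concatenates the
#' coefficients coarsest-first: `[approx | detail_jmax | ... | detail_1]`.
#' This fixed ordering makes downstream stepwise-selection results
#' reproducible. Column names are `wc_L{jmax}_a{k}` for the approximation
#' and `wc_L{j}_{k}` for detail coefficients.
#'
#' @param samples A [labeled_samples()] with 80 band features.
#' @return A [labeled_samples()] with 111 wavelet-coefficient features and
#'   the same labels, image ids and role (no wavelength table).
#' @export
coefficient_features <- function(samples) {
  stopifnot(inherits(samples, "labeled_samples"))
  if (ncol(samples$spectra) != 80L)
    stop("expected 80 band features, got ", ncol(samples$spectra),
         call. = FALSE)
  d1 <- dwt(samples$spectra[1L, ])
  n_out <- sum(d1$level_lengths) + length(d1$approx_coeffs)
  flatten <- function(d)
    c(d$approx_coeffs, unlist(rev(d$detail_coeffs), use.names = FALSE))
  out <- t(apply(samples$spectra, 1L, function(r) flatten(dwt(r))))
  if (nrow(samples$spectra) == 1L) out <- matrix(out, nrow = 1L)
  jmax <- d1$levels
  nm <- c(sprintf("wc_L%d_a%d", jmax, seq_along(d1$approx_coeffs)),
          unlist(lapply(rev(seq_len(jmax)), function(j)
            sprintf("wc_L%d_%d", j, seq_len(d1$level_lengths[j])))))
  colnames(out) <- nm
  stopifnot(ncol(out) == n_out)
  labeled_samples(out, samples$labels, samples$image_ids,
                  feature_wavelengths = NULL, role = samples$role,
                  class_set = samples$class_set)
}
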