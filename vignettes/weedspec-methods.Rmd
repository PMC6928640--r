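---
title: "Discriminating crop and weed pixels from field imaging-spectrometer data"
author: "weedspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating crop and weed pixels from field imaging-spectrometer data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(weedspec)
```

## The problem

A line-scanning field imaging spectrometer records, for every ground pixel
of roughly 1 mm at a 1 m platform height (`ground_resolution()`), a 344-band
spectrum of raw digital numbers (DN) between 379 and 870 nm, quantized to
12 bits. The task is to tell a crop (carrot seedlings) apart from three
weed species — purslane, goosegrass and humifuse — pixel by pixel, under
natural light that drifts with cloud cover between acquisitions. Two
practical constraints shape the method:

* **No reflectance calibration.** Standard panels cannot be measured in
  real time in the field, so classification must work on (normalized) DN,
  not reflectance.
* **Dimensionality.** 344 correlated channels are heavily redundant; a
  deployable instrument wants the handful of bands that do the work.

`weedspec` implements the full chain — preprocessing, feature
construction (raw bands and wavelet coefficients), Wilks'-statistic
stepwise feature selection, and Fisher LDA / RBF-SVM classification —
together with a synthetic scene generator that reproduces the statistical
structure the method assumes, so every stage is testable without access
to the original (undeposited) imagery.

## Preprocessing

1. **Trim** (`trim_bands()`): wavelengths below 410 nm are discarded for
   low signal-to-noise; on the instrument's grid this retains 320 of 344
   bands.
2. **Average** (`average_bands()`): blocks of 4 adjacent bands are
   averaged, giving 80 bands and reducing noise. A trailing remainder that
   does not fill a block is dropped with a warning (the canonical 320
   divides evenly).
3. **Normalize** (`normalize_spectrum()`): each spectrum is divided by its
   own mean. Under the acquisition model a change in illumination is a
   single multiplicative scalar per pixel spectrum, so the normalized
   spectrum (mean exactly 1) is illumination-invariant; the operation is
   idempotent and scale-invariant to 1e-12 relative tolerance.
4. **Soil masking** (`compute_ndvi()`, `threshold_plants()`): NDVI
   `(DN_NIR - DN_R)/(DN_NIR + DN_R)` is computed from the averaged bands
   nearest 760 and 660 nm (ties to the lower wavelength — the lookup must
   be deterministic after averaging shifts band centers). The plant/soil
   threshold comes from Otsu's between-class-variance maximization on a
   256-bin histogram over [-1, 1]; we chose Otsu because it is the
   canonical deterministic, parameter-free bimodal-histogram method, and a
   manual override is provided. The threshold is computed per image
   (illumination differs between acquisitions); pixels with a zero NDVI
   denominator are flagged and never counted as vegetation.

The pipeline fixes the order trim → average → normalize; NDVI is computed
on the averaged 80-band data.

## Features

**Raw bands.** The 80 averaged, normalized bands.

**Wavelet coefficients** (`dwt()`, `coefficient_features()`). Each
80-band spectrum is decomposed with the Daubechies db3 wavelet (filter
length L = 6, three vanishing moments) in a convolution pyramid with
half-point symmetric boundary extension. Each level's output length is
`floor((n - 1)/2) + L/2`, and decomposition continues while the running
approximation is longer than L − 1 = 5. From 80 samples this produces
detail levels of length 42, 23, 14, 9, 7, 6, 5 plus a final approximation
of length 5: **111 coefficients**, concatenated coarsest-first
(`[approx | detail_7 | … | detail_1]`) in a fixed, documented order so
that selection results are reproducible. This boundary/length convention
is the one under which an 80-sample db3 decomposition yields exactly that
count; the transform is exactly invertible (`inverse_dwt()`), linear, and
annihilates constants up to numerical noise.

Two numerical caveats are deliberate:

* The boundary extension makes the transform slightly redundant (84
  coefficients from 80 samples at level 1), so Parseval's identity holds
  only up to a small boundary inflation; tests bound it rather than
  assert exact energy conservation.
* The per-level "energy" summary (`level_energy()`) is provided in two
  modes: `as_printed`, the plain mean of the coefficients (the quantity's
  published definition, which can be negative), and `squared`, the
  conventional mean square. Neither is consumed downstream —
  classification uses the coefficients themselves — so the as-printed
  form is kept as the default for fidelity.

## Feature selection

Class structure is summarized by deviation (scatter) matrices
(`scatter_matrices()`): within-class `Sw`, total `Sm`, and between-class
`Sb = Sm − Sw`. The separability of a feature subset is the determinant
ratio `J = |Sm| / |Sw|` (`separability()`); its reciprocal is Wilks'
Λ. `J ≥ 1`, grows as class means separate, and is invariant to
translation and to any common invertible linear map of the features.
Determinants are evaluated in log space via Cholesky factorization —
scatter determinants on 80+ features overflow doubles long before the
ratio does — with singularity declared when a pivot falls below
`1e-10 × scale`.

`stepwise_select()` is classical stepwise discriminant selection. The
candidate maximizing the entry partial-F

    F = ((n − g − p) / (g − 1)) · (1 − λ) / λ,   λ = Λ_{p+1} / Λ_p

(n samples, g classes, p features already selected) enters while
`F > F_enter`; after each entry, any selected feature whose removal
partial-F drops below `F_remove` leaves again (the just-entered feature
is exempt within its own step, which prevents cycling). The defaults
`F_enter = 3.84`, `F_remove = 2.71` are the conventional
stepwise-discriminant thresholds; ties break to the lowest feature index
so selection is deterministic. Removal can be disabled for pure forward
selection. `exhaustive_select()` provides a brute-force oracle for small
problems; the greedy path is not guaranteed optimal, and tests assert a
regression floor (final J within 10% of the exhaustive optimum in ≥ 90%
of seeded trials) rather than optimality.

## Classification

**Fisher LDA** (`fit_lda()`, `predict_lda()`), written from first
principles. Projection axes maximize `J(w) = (w′ Sb w)/(w′ Sw w)`; the
generalized eigenproblem is solved by whitening (Cholesky of `Sw`) and a
symmetric eigendecomposition — a numerically stable and deterministic
route — keeping up to `g − 1` axes in decreasing-eigenvalue order with a
fixed sign convention. A sample is assigned the class of the nearest
projected class center (Euclidean), ties to the earlier class in
`class_order`. LDA is affine-invariant, so it consumes unstandardized
features.

One degenerate case matters: after mean normalization every spectrum
satisfies one exact linear constraint (its bands sum to `N`), so at the
*full* feature dimension `Sw` is exactly singular — likewise for the full
redundant 111-coefficient wavelet expansion. `fit_lda(ridge =)` adds a
small relative ridge `ridge · mean(diag(Sw)) · I` for exactly this case;
the pipeline uses `1e-6` at the full dimension only, and the strict
default (`ridge = 0`) turns singular `Sw` into an error that points the
user to feature selection.

**RBF-SVM** (`tune_and_fit_svm()`, backed by libsvm through e1071 with
the library-standard one-vs-one multiclass scheme). Because the RBF
kernel is scale-sensitive, features are standardized to train-set
mean/variance (stored, re-applied at prediction); `(C, γ)` come from a
seeded stratified cross-validated grid search over geometric grids
(defaults `C ∈ 2^{-5..15}`, `γ ∈ 2^{-15..3}`, 5-fold, the libsvm
practical-guide convention), ties to the smaller C then the smaller γ.
Grid search uses cross-validation on the training samples only — the
validation images never touch tuning.

`evaluate()` reports the confusion matrix, per-class recall (%) and
pooled overall accuracy (%). With the design's balanced per-class
validation counts, pooled overall accuracy coincides with the mean of
per-class accuracies (asserted in tests), so either summary can be
compared across arms.

## The synthetic scene generator

No imagery is deposited with the study this design emulates, so
`generate_scene()` is a first-class, tested module that produces the
nuisances the method is built to remove — not a radiative-transfer model.

* **Templates** (`make_class_templates()`): piecewise-smooth parametric
  reflectance — Gaussian absorption wells at 450 and 660 nm, a green bump
  at 550 nm, a logistic red edge, a flat NIR plateau; soil is a smooth
  monotone ramp (NDVI < 0.2). The defaults make purslane and goosegrass
  the most similar pair, preserving the qualitative per-class difficulty
  ordering of the field problem. The analysis needs class-separable,
  red-edge-bearing spectra, not biophysical fidelity.
* **Wavelength grid** (`fiss_wavelengths()`): 344 bands spanning
  379–870 nm at a mean interval of ~1.4 nm, with mildly nonuniform
  dispersion (24 bands below 410 nm, 320 above) so the published
  band-count arithmetic — 344 → 320 → 80 — holds exactly on the default
  grid.
* **Illumination**: one log-normal multiplicative scalar per acquisition
  (default `sdlog = 0.25`, a free parameter documented rather than fitted
  — the emulated campaign reports no variability figure) times a fixed
  smooth spectral tilt. This is exactly the nuisance mean normalization
  removes, and the invariance is tested by construction.
* **Within-class variability**: each plant pixel perturbs its class
  template (red-edge position sd 2.5 nm, slope sd 1 nm, NIR plateau sd
  0.03, visible baseline sd 0.008) — without it every same-class pixel
  would be identical up to sensor noise and the task would be trivially
  separable. Zeroing `within_class_sd` recovers the pixel-exact regime
  used by several invariance tests.
* **Sensor**: additive Gaussian noise (default sd 3 DN, consistent with a
  high-SNR instrument), gain 3200 counts per unit reflectance, 12-bit
  clipping and rounding.
* **Layout**: square vegetation patches on soil, every class forced
  present in every image; default cover 15/10/10/10% plants, 55% soil.

All randomness flows through explicit seeds (`set.seed` at entry;
per-image sub-seeds drawn once), so every operation is bit-reproducible.

What passing tests on this generator do **not** show: robustness to
shadowing, plant overlap and morphology, BRDF effects, sensor spectral
response, or real biological variance structure. The generator produces
cleaner class structure than field data, so absolute accuracies on
synthetic scenes run higher than one should expect in the field; the
qualitative claims (plateau of accuracy with feature count, wavelet
advantage at very small feature counts, SVM ≥ LDA under nonlinear
structure, red-edge bands selected first) are the transferable content.

## The experiment harness

`run_experiment()` wires the stages: simulate an acquisition series,
split it into disjoint train/validation image sets (the emulated design
is 20/20 out of 41, with 3000 pixels per class per role = 12,000 + 12,000
samples), preprocess, build features, select on training data only, then
fit and evaluate every configured (feature type × model × feature count)
cell on validation data only. Reported feature counts default to 1–20
plus the full dimension, mirroring the published table layout
(`accuracy_table()`, `format_accuracy_text()`), and
`difference_table()` produces the wavelet-minus-bands and SVM-minus-LDA
comparisons. Determinism is end-to-end: one master seed derives all stage
seeds, and identical configs serialize to identical reports.

The package's own test harness exercises scaled-down problem sizes chosen
to keep the full suite fast while preserving the statistical properties
under test: 24–32 pixel square scenes, 6–12 images, 60–200 pixels per
class, feature counts up to 8, reduced SVM grids; the full 41-image,
3000-per-class sampling design is exercised once for its counts. These
sizes are the package's choices for routine verification; nothing in the
method depends on them.

## Known limitations

* The ENVI reader/writer supports one canonical dialect (BSQ, unsigned
  16-bit little-endian, wavelengths in the header) — deliberately, to
  avoid interleave ambiguity; it is not a general ENVI implementation.
* Only the db3 mother wavelet is provided; the published comparison of
  Daubechies orders found differences minimal, and the fixed filter keeps
  the coefficient count and ordering stable.
* Whether the original selection used removal steps is not recorded;
  both are implemented, removal on by default, and pure forward selection
  is one flag away.
* `exhaustive_select()` is an oracle for tests, capped by subset count;
  it is not a practical selector at 80+ features.
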