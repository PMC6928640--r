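# weedspec

Pixel-level crop/weed discrimination from field imaging-spectrometer
data. The package is for researchers in precision agriculture and
hyperspectral image analysis who need to (a) find the few spectral bands
that separate a crop from weed species under uncalibrated, drifting field
illumination, and (b) quantify how feature choice (raw bands vs wavelet
coefficients) and classifier choice (linear vs kernel) affect per-species
accuracy.

The scenario it models: a line-scanning spectrometer (380–870 nm, 344
bands, 12-bit DN) imaging carrot seedlings infested with purslane,
goosegrass and humifuse, under cloud cover that changes between
acquisitions so no reflectance calibration is possible.

## Method

* **Preprocessing** — discard bands below 410 nm (320 remain), average
  blocks of 4 adjacent bands (80 remain), then mean-normalize each pixel
  spectrum, `DN_i' = DN_i / ((1/N) Σ_k DN_k)`, which cancels the per-pixel
  multiplicative illumination scalar. Soil is removed by thresholding
  `NDVI = (DN_NIR − DN_R)/(DN_NIR + DN_R)` (bands nearest 760/660 nm)
  with Otsu's histogram method.
* **Features** — the 80 bands themselves, or the 111 coefficients of the
  multilevel db3 discrete wavelet transform of each 80-band spectrum
  (half-point symmetric extension, per-level length `floor((n−1)/2)+3`,
  decomposed while the approximation exceeds length 5: details
  42+23+14+9+7+6+5 plus a length-5 approximation).
* **Selection** — scatter-matrix separability `J = |Sm|/|Sw|` (its
  reciprocal is Wilks' Λ) drives classical stepwise discriminant
  selection with entry/removal partial-F tests
  `F = ((n−g−p)/(g−1))·(1−λ)/λ`, `λ = Λ_{p+1}/Λ_p`.
* **Classification** — Fisher LDA maximizing `J(w) = (w′S_b w)/(w′S_w w)`
  with nearest projected-class-center assignment, and an RBF-kernel SVM
  tuned by seeded cross-validated grid search; accuracy is reported per
  class and overall against held-out validation images.
* **Synthetic scenes** — a seeded generator produces FISS-like cubes
  (class-specific red-edge reflectance templates, per-acquisition
  log-normal illumination, per-pixel biological jitter, sensor noise,
  12-bit quantization, soil background with ground truth), so the entire
  chain is testable without the original imagery.

## Worked example

Simulate a 12-image campaign, select bands on 6 training images, evaluate
LDA on 6 held-out validation images:

```r
library(weedspec)

cfg <- experiment_config(
  scene = scene_config(image_size = c(32L, 32L), patch_px = 8L),
  n_images = 12L, n_train_images = 6L, n_validation_images = 6L,
  n_per_class = 150L, feature_types = c("bands", "wavelet"),
  feature_counts = c(1, 2, 4, 8), models = "lda", seed = 42L)
report <- run_experiment(cfg)

wl80 <- average_bands(trim_bands(labeled_samples(
  matrix(1, 1, 344), "carrot", "x",
  feature_wavelengths = fiss_wavelengths())))$feature_wavelengths
round(wl80[report$selection$bands$selected])
#> [1] 718 724 614 545 654 758 597 608

format_accuracy_text(report, "bands")
#> k  carrot_LDA  goosegrass_LDA  humifuse_LDA  purslane_LDA  overall_LDA
#> 1  82.7        66.7            96.7          60.0          76.5
#> 2  91.3        72.0            94.0          72.0          82.3
#> 4  93.3        88.7            98.0          90.0          92.5
#> 8  99.3        99.3            100.0         100.0         99.7

round(difference_table(report, "feature_type", within = "lda"), 1)
#>               1    2    4    8
#> carrot      2.7  4.7  5.3  0.7
#> goosegrass 15.3 15.3 10.7  0.7
#> humifuse    2.7  6.0  2.0  0.0
#> purslane   22.0 14.7  8.0 -0.7
#> overall    10.7 10.2  6.5  0.2
```

Reading the output: the first two selected band centers (718 and 724 nm)
sit on the vegetation red edge, the steep chlorophyll-driven reflectance
rise that carries most of the species signal; accuracy climbs steeply to
k ≈ 4–8 features and then plateaus; and the wavelet-minus-bands
difference table shows wavelet coefficients ahead by ~10 overall points
when only 1–2 features are allowed, an advantage that vanishes as more
features enter. Purslane and goosegrass — the most spectrally similar
pair in the scene model — are the hardest classes at small k. Synthetic
scenes are cleaner than field data, so absolute accuracies are optimistic;
the structure of the curves is the reproducible content.

A command-line wrapper with the same stages is provided at
`inst/scripts/run_experiment.R`.

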