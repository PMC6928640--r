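Package: weedspec
Title: Crop/Weed Discrimination from Field Imaging-Spectrometer Pixel Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for discriminating crop and weed species
    from hyperspectral pixel spectra acquired by a field imaging spectrometer
    (380-870 nm, 344 bands, 12-bit). Provides ENVI cube I/O, a synthetic-scene
    generator with class-specific red-edge reflectance templates and
    illumination drift, the preprocessing chain (band trimming, 4-band
    averaging, mean normalization, NDVI/Otsu soil masking), db3 discrete
    wavelet transform feature extraction, Wilks'-statistic stepwise feature
    selection based on scatter-matrix separability, and Fisher linear
    discriminant analysis plus RBF-kernel support vector machine classifiers
    with grid-search tuning and accuracy reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
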