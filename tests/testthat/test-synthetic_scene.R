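test_that("plant templates have pigment wells, red edge and NIR plateau", {
  cfg <- tiny_scene()
  tpl <- make_class_templates(cfg)
  wl <- cfg$wavelengths
  expect_true(all(tpl >= 0 & tpl <= 1))
  for (k in names(cfg$classes)) {
    at <- function(nm) tpl[which.min(abs(wl - nm)), k]
    expect_gt(at(800), at(660))                      # red edge rise
    expect_gt(at(550), at(450))                      # green bump vs blue well
    # monotone rise through the red-edge window
    win <- wl >= 690 & wl <= 740
    expect_true(all(diff(tpl[win, k]) > 0))
  }
  soil <- tpl[, "soil"]
  expect_true(all(diff(soil) > 0))                   # monotone ramp
})

test_that("curve difference of red-edge-shifted twins peaks inside 690-740 nm", {
  cls <- default_class_params()
  a <- cls$carrot
  b <- a; b$red_edge_nm <- a$red_edge_nm + 10
  cfg <- tiny_scene(classes = list(x = a, y = b),
                    plant_cover_fraction = c(x = 0.2, y = 0.2))
  tpl <- make_class_templates(cfg)
  peak <- cfg$wavelengths[which.max(abs(tpl[, "x"] - tpl[, "y"]))]
  expect_gte(peak, 690)
  expect_lte(peak, 740)
})

test_that("soil template NDVI from its 760/660 nm values is below 0.2", {
  cfg <- tiny_scene()
  tpl <- make_class_templates(cfg)
  wl <- cfg$wavelengths
  nir <- tpl[which.min(abs(wl - 760)), "soil"]
  red <- tpl[which.min(abs(wl - 660)), "soil"]
  expect_lt((nir - red) / (nir + red), 0.2)
})

test_that("templates leaving [0,1] raise a config error", {
  cls <- default_class_params()
  cls$carrot$nir_plateau <- 1.4
  expect_error(tiny_scene(classes = cls), "\\[0, 1\\]")
})

test_that("cover fractions must be positive and sum below 1", {
  expect_error(tiny_scene(plant_cover_fraction = c(carrot = 0.5,
                                                   purslane = 0.3,
                                                   goosegrass = 0.2,
                                                   humifuse = 0.2)),
               "sum")
})

test_that("generate_scene is seed-deterministic with every class present", {
  cfg <- tiny_scene()
  a <- generate_scene(cfg, seed = 11)
  b <- generate_scene(cfg, seed = 11)
  expect_identical(a$cube$dn, b$cube$dn)
  expect_identical(a$truth$labels, b$truth$labels)
  expect_true(all(names(cfg$classes) %in% a$truth$labels))
  c2 <- generate_scene(cfg, seed = 12)
  expect_false(identical(a$cube$dn, c2$cube$dn))
})

test_that("noise-free fixed-illumination scenes give identical same-class pixels", {
  cfg <- tiny_scene(noise_sd = 0,
                    within_class_sd = list(red_edge_nm = 0,
                                           red_edge_slope = 0,
                                           nir_plateau = 0, vis_base = 0),
                    illumination = list(sdlog = 0.25, shape_slope = 0.15,
                                        fixed_scale = 1))
  sc <- generate_scene(cfg, seed = 5)
  px <- extract_pixels(sc$cube, sc$truth$labels == "carrot")
  expect_gt(nrow(px), 1)
  expect_equal(max(apply(px, 2, function(cc) diff(range(cc)))), 0)
})

test_that("illumination is a pure multiplicative scalar before quantization", {
  mk <- function(scale) tiny_scene(
    noise_sd = 0,
    illumination = list(sdlog = 0.25, shape_slope = 0.15,
                        fixed_scale = scale))
  a <- generate_scene(mk(0.5), seed = 5, quantize = FALSE)
  b <- generate_scene(mk(1.0), seed = 5, quantize = FALSE)
  expect_equal(b$cube$dn, 2 * a$cube$dn, tolerance = 1e-12)
})

test_that("normalization cancels illumination drift by construction", {
  # the invariance that justifies mean-normalization: same pixel under two
  # illumination scalars normalizes to the same spectrum
  mk <- function(scale) tiny_scene(
    noise_sd = 0,
    illumination = list(sdlog = 0.25, shape_slope = 0.15,
                        fixed_scale = scale))
  a <- generate_scene(mk(0.7), seed = 5)
  b <- generate_scene(mk(1.3), seed = 5)
  pa <- extract_pixels(a$cube, a$truth$labels != "soil")
  pb <- extract_pixels(b$cube, b$truth$labels != "soil")
  for (i in c(1, 5, 10)) {
    na <- normalize_spectrum(pa[i, ])
    nb <- normalize_spectrum(pb[i, ])
    # agreement up to DN rounding: one DN out of O(300) per band
    expect_lt(max(abs(na - nb)), 0.02)
  }
})

test_that("acquisition series draws independent illumination per image", {
  cfg <- tiny_scene()
  series <- generate_acquisition_series(cfg, 5, seed = 21)
  expect_length(series, 5)
  ids <- vapply(series, function(s) s$cube$acquisition_id, character(1))
  expect_equal(anyDuplicated(ids), 0L)
  scales <- vapply(series, function(s) s$truth$illumination_scale,
                   numeric(1))
  expect_gt(length(unique(scales)), 1)
  again <- generate_acquisition_series(cfg, 5, seed = 21)
  expect_identical(series[[3]]$cube$dn, again[[3]]$cube$dn)
  expect_length(generate_acquisition_series(cfg, 1, seed = 1), 1)
  expect_error(generate_acquisition_series(cfg, 0, seed = 1), ">= 1")
})

test_that("sample_pixels honours the train/validation design", {
  cfg <- tiny_scene()
  series <- generate_acquisition_series(cfg, 6, seed = 8)
  ids <- sprintf("img%03d", 1:6)
  roles <- sample_pixels(series, 20, ids[1:3], ids[4:6], seed = 2)
  for (r in roles) {
    expect_equal(nrow(r$spectra), 20 * 4)
    expect_true(all(table(r$labels) == 20))
  }
  expect_true(all(roles$train$image_ids %in% ids[1:3]))
  expect_true(all(roles$validation$image_ids %in% ids[4:6]))
  expect_length(intersect(roles$train$image_ids,
                          roles$validation$image_ids), 0)
  # single pixel per class
  one <- sample_pixels(series, 1, ids[1:3], ids[4:6], seed = 2)
  expect_equal(nrow(one$train$spectra), 4)
  # overlapping sets rejected; absent class rejected; deficit named
  expect_error(sample_pixels(series, 5, ids[1:3], ids[3:6], seed = 2),
               "disjoint")
  expect_error(sample_pixels(series, 5, ids[1:3], ids[4:6], seed = 2,
                             classes = c("carrot", "dandelion")),
               "dandelion")
  expect_error(sample_pixels(series, 1e6, ids[1:3], ids[4:6], seed = 2),
               "only")
})
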