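test_that("scatter matrices match hand-derived deviation sums", {
  # 1-D two-class data {0,0} vs {1,1}: Sw = 0, Sm = 4 * 0.25 = 1
  s <- labeled_samples(matrix(c(0, 0, 1, 1)), c("a", "a", "b", "b"),
                       rep("i", 4))
  st <- scatter_matrices(s)
  expect_equal(unname(st$Sw), matrix(0))
  expect_equal(unname(st$Sm), matrix(1))
  expect_equal(unname(st$Sb), matrix(1))
  # classes {-1, 1} and {9, 11}: Sw = 4, Sm = 36+16+16+36 = 104, J = 26
  s2 <- labeled_samples(matrix(c(-1, 1, 9, 11)), c("a", "a", "b", "b"),
                        rep("i", 4))
  st2 <- scatter_matrices(s2)
  expect_equal(unname(st2$Sw), matrix(4))
  expect_equal(unname(st2$Sm), matrix(104))
  expect_equal(separability(st2), 26)
})

test_that("identical class means give Sb = 0 and J = 1", {
  set.seed(2)
  X <- matrix(rnorm(40), 20, 2)
  X2 <- rbind(X, X)  # second class is an exact copy: same mean
  s <- labeled_samples(X2, rep(c("a", "b"), each = 20), rep("i", 40))
  st <- scatter_matrices(s)
  expect_equal(max(abs(st$Sb)), 0, tolerance = 1e-9)
  expect_equal(separability(st), 1, tolerance = 1e-9)
})

test_that("scatter matrices are translation invariant, symmetric PSD, Sm = Sw + Sb", {
  set.seed(3)
  means <- rbind(a = c(0, 0, 0), b = c(1, 0.5, -1), c = c(-1, 1, 0))
  s <- gaussian_samples(15, means, seed = 3)
  st <- scatter_matrices(s)
  shift <- labeled_samples(sweep(s$spectra, 2, c(100, -50, 7), "+"),
                           s$labels, s$image_ids)
  st2 <- scatter_matrices(shift)
  expect_equal(st$Sw, st2$Sw, tolerance = 1e-8)
  expect_equal(st$Sm, st2$Sm, tolerance = 1e-8)
  expect_equal(st$Sm, st$Sw + st$Sb, tolerance = 1e-10)
  expect_equal(st$Sw, t(st$Sw))
  expect_true(all(eigen(st$Sw, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-9))
  expect_error(scatter_matrices(
    labeled_samples(matrix(1:4), c("a", "a", "a", "a"), rep("i", 4))),
    "2 classes")
  expect_error(scatter_matrices(s, feature_subset = c(1, 1)), "distinct")
})

test_that("a duplicated feature makes Sw singular and is reported", {
  set.seed(4)
  s <- gaussian_samples(10, rbind(a = c(0, 0), b = c(2, 1)), seed = 4)
  dup <- labeled_samples(cbind(s$spectra, s$spectra[, 1]), s$labels,
                         s$image_ids)
  expect_error(separability(scatter_matrices(dup)), "singular")
})

test_that("J is invariant to per-feature positive scaling (property)", {
  set.seed(6)
  for (i in 1:10) {
    s <- gaussian_samples(12, rbind(a = rnorm(4), b = rnorm(4),
                                    c = rnorm(4)), seed = i)
    J1 <- separability(scatter_matrices(s))
    sc <- runif(4, 0.1, 10)
    s2 <- labeled_samples(sweep(s$spectra, 2, sc, "*"), s$labels,
                          s$image_ids)
    J2 <- separability(scatter_matrices(s2))
    expect_equal(J1, J2, tolerance = 1e-7)
    expect_gte(J1, 1 - 1e-9)
  }
})

test_that("the first stepwise feature equals the exhaustive single-feature argmax", {
  for (seed in 1:12) {
    set.seed(seed)
    d <- 10
    means <- matrix(rnorm(3 * d, sd = 0.8), 3, d,
                    dimnames = list(c("a", "b", "c"), NULL))
    s <- gaussian_samples(25, means, seed = seed + 100)
    sel <- stepwise_select(s, max_features = 1)
    expect_equal(sel$selected, exhaustive_select(s, 1),
                 info = paste("seed", seed))
  }
})

test_that("stepwise selection recovers planted discriminative features", {
  hits <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    d <- 25
    means <- matrix(0, 4, d, dimnames = list(letters[1:4], NULL))
    means[, 5] <- c(0, 2, -2, 1)    # class differences only at 5 and 17
    means[, 17] <- c(-1, 1, 2, -2)
    s <- gaussian_samples(30, means, seed = seed + 500)
    sel <- stepwise_select(s, max_features = 2)
    if (setequal(sel$selected, c(5L, 17L))) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("Wilks Lambda is non-increasing and J = 1/Lambda along forward steps", {
  for (seed in 1:15) {
    means <- matrix(rnorm(3 * 8, sd = 0.5), 3, 8,
                    dimnames = list(c("a", "b", "c"), NULL))
    s <- gaussian_samples(20, means, seed = seed)
    sel <- stepwise_select(s, max_features = 6, F_enter = 0.01,
                           F_remove = 0.005)
    expect_true(all(diff(sel$wilks_trace) <= 1e-12))
    expect_equal(sel$J_trace, 1 / sel$wilks_trace, tolerance = 1e-9)
    expect_true(all(sel$J_trace >= 1 - 1e-9))
  }
})

test_that("selection is deterministic and respects F_enter", {
  s <- gaussian_samples(20, rbind(a = c(0, 0, 0), b = c(1, 2, 0.5)),
                        seed = 9)
  a <- stepwise_select(s, max_features = 3)
  b <- stepwise_select(s, max_features = 3)
  expect_identical(a$selected, b$selected)
  expect_message(empty <- stepwise_select(s, max_features = 3,
                                          F_enter = Inf, F_remove = 1),
                 "empty selection")
  expect_length(empty$selected, 0)
  expect_error(stepwise_select(s, max_features = 99), "exceeds")
  expect_error(stepwise_select(s, max_features = 2, F_enter = 1,
                               F_remove = 2), "F_enter")
})

test_that("greedy stepwise J stays near the exhaustive optimum (regression floor)", {
  ok <- 0L; trials <- 30L
  for (seed in seq_len(trials)) {
    means <- matrix(rnorm(3 * 9, sd = 0.6), 3, 9,
                    dimnames = list(c("a", "b", "c"), NULL))
    s <- gaussian_samples(15, means, seed = seed + 900)
    sel <- stepwise_select(s, max_features = 3, F_enter = 0.01,
                           F_remove = 0.005)
    if (length(sel$selected) < 3) next
    J_greedy <- separability(scatter_matrices(s, sel$selected))
    J_best <- separability(scatter_matrices(s, exhaustive_select(s, 3)))
    if (J_greedy >= 0.9 * J_best) ok <- ok + 1L
  }
  expect_gte(ok / trials, 0.9)
})

test_that("exhaustive_select edge cases: k = d, cap, ties", {
  s <- gaussian_samples(12, rbind(a = c(0, 0, 0), b = c(1, 0.5, 2)),
                        seed = 31)
  expect_equal(exhaustive_select(s, 3), 1:3)
  expect_error(exhaustive_select(s, 2, cap = 1), "cap")
})

test_that("selection results serialize to JSON with wavelengths in order", {
  s <- gaussian_samples(15, rbind(a = c(0, 0, 0), b = c(2, 0.2, 1)),
                        seed = 41)
  sel <- stepwise_select(s, max_features = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_selection_json(sel, path, wavelengths = c(585, 714, 608))
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$selected, sel$selected)
  expect_equal(back$selected_wavelengths_nm,
               c(585, 714, 608)[sel$selected])
})
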