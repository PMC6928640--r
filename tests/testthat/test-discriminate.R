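test_that("two spherical classes recover the closed-form Fisher direction", {
  set.seed(61)
  d <- 6
  mu1 <- rnorm(d); mu2 <- mu1 + c(3, -2, 1, 0.5, 0, 1.5)
  s <- gaussian_samples(400, rbind(a = mu1, b = mu2), sd = 1, seed = 61)
  m <- fit_lda(s)
  w <- m$W[, 1]
  st <- scatter_matrices(s)
  closed <- solve(st$Sw, colMeans(s$spectra[s$labels == "b", ]) -
                    colMeans(s$spectra[s$labels == "a", ]))
  cosine <- abs(sum(w * closed)) / sqrt(sum(w^2) * sum(closed^2))
  expect_gte(cosine, 0.999)
})

test_that("axis count is capped at g - 1 and eigenvalues are sorted", {
  means <- rbind(a = c(0, 0, 0, 0, 0), b = c(1, 0, 0, 0, 0),
                 c = c(0, 1, 0, 0, 0), d = c(0, 0, 1, 0, 0))
  s <- gaussian_samples(30, means, seed = 62)
  m <- fit_lda(s)
  expect_equal(ncol(m$W), 3L)                 # four classes -> <= 3 axes
  expect_equal(nrow(m$projected_centers), 4L)
  expect_true(all(diff(m$eigenvalues) <= 1e-9))
})

test_that("duplicated feature columns raise the singular-Sw error", {
  s <- gaussian_samples(20, rbind(a = c(0, 0), b = c(2, 1)), seed = 63)
  dup <- labeled_samples(cbind(s$spectra, s$spectra[, 2]), s$labels,
                         s$image_ids)
  expect_error(fit_lda(dup), "singular")
})

test_that("predict_lda assigns training class means to their own class", {
  means <- rbind(a = c(0, 0), b = c(4, 0), c = c(0, 4))
  s <- gaussian_samples(50, means, seed = 64)
  m <- fit_lda(s)
  pred <- predict_lda(m, means)
  expect_equal(pred, rownames(means))
  expect_error(predict_lda(m, matrix(0, 2, 5)), "width")
})

test_that("exact ties go to the earlier class in class_order", {
  # mirror-symmetric classes: projected centers are exactly +/- a, so the
  # origin is equidistant to both in floating point
  X <- rbind(c(-1, 1), c(-3, -1), c(1, 1), c(3, -1))
  s <- labeled_samples(X, c("first", "first", "second", "second"),
                       rep("i", 4))
  m <- fit_lda(s)
  expect_equal(predict_lda(m, matrix(c(0, 0), 1, 2)), "first")
})

test_that("LDA validation accuracy approaches the analytic Bayes accuracy", {
  # two spherical unit-variance Gaussians at Mahalanobis separation Delta:
  # Bayes accuracy = pnorm(Delta / 2)
  delta <- 2
  mu2 <- c(delta, 0, 0)
  tr <- gaussian_samples(2000, rbind(a = c(0, 0, 0), b = mu2), seed = 65)
  va <- gaussian_samples(2000, rbind(a = c(0, 0, 0), b = mu2), seed = 66,
                         role = "validation")
  m <- fit_lda(tr)
  acc <- evaluate(predict_lda(m, va), va$labels,
                  m$class_order)$overall_accuracy
  bayes <- 100 * pnorm(delta / 2)
  expect_lt(abs(acc - bayes), 2)
})

test_that("LDA axes are invariant to per-feature scaling (up to sign/scale)", {
  s <- gaussian_samples(100, rbind(a = c(0, 0, 0), b = c(2, 1, -1)),
                        seed = 67)
  m1 <- fit_lda(s)
  sc <- c(0.2, 5, 1.7)
  s2 <- labeled_samples(sweep(s$spectra, 2, sc, "*"), s$labels, s$image_ids)
  m2 <- fit_lda(s2)
  # w2 should align with w1 / sc after undoing the feature scaling
  w1 <- m1$W[, 1] / sc
  w2 <- m2$W[, 1]
  cosine <- abs(sum(w1 * w2)) / sqrt(sum(w1^2) * sum(w2^2))
  expect_gte(cosine, 0.9999)
  # and predictions are identical on correspondingly scaled data
  expect_identical(predict_lda(m1, s$spectra), predict_lda(m2, s2$spectra))
})

test_that("fit_lda agrees with an independent reference implementation", {
  s <- gaussian_samples(150, rbind(a = c(0, 0, 0, 0), b = c(1.5, 1, 0, -1),
                                   c = c(-1, 0.5, 1, 0)), seed = 68)
  m <- fit_lda(s)
  ref <- MASS::lda(s$spectra, grouping = s$labels)
  # discriminant subspaces coincide: each reference axis is (up to scale)
  # in the span of ours, checked via projection residual
  W <- m$W
  for (j in 1:2) {
    v <- ref$scaling[, j]
    resid <- v - W %*% solve(crossprod(W), crossprod(W, v))
    expect_lt(sqrt(sum(resid^2)) / sqrt(sum(v^2)), 1e-6)
  }
  # and predictions agree where the reference is confident
  pred_ref <- as.character(predict(ref, s$spectra)$class)
  expect_gt(mean(pred_ref == predict_lda(m, s)), 0.98)
})

test_that("SVM grid search separates separable data and is seed-deterministic", {
  s <- gaussian_samples(30, rbind(a = c(0, 0), b = c(8, 8)), seed = 71)
  spec <- svm_spec(C_grid = 2^c(-1, 1, 3), gamma_grid = 2^c(-3, -1),
                   cv_folds = 3, seed = 5)
  m <- tune_and_fit_svm(s, spec)
  expect_equal(max(m$cv_table$cv_accuracy), 1)
  expect_identical(predict_svm(m, s), s$labels)
  m2 <- tune_and_fit_svm(s, spec)
  expect_identical(c(m$chosen_C, m$chosen_gamma),
                   c(m2$chosen_C, m2$chosen_gamma))
  expect_error(tune_and_fit_svm(s, svm_spec(cv_folds = 50)), "cv_folds")
  expect_error(svm_spec(C_grid = numeric(0)), "nonempty")
  expect_error(svm_spec(gamma_grid = c(-1, 1)), "positive")
})

test_that("RBF-SVM beats LDA on the XOR construction", {
  tr <- xor_samples(seed = 72)
  va <- xor_samples(seed = 73, role = "validation")
  lda_m <- fit_lda(tr)
  lda_acc <- evaluate(predict_lda(lda_m, va), va$labels,
                      lda_m$class_order)$overall_accuracy
  svm_m <- tune_and_fit_svm(tr, svm_spec(C_grid = 2^c(0, 2, 4),
                                         gamma_grid = 2^c(-4, -2, 0),
                                         cv_folds = 3, seed = 1))
  svm_acc <- evaluate(predict_svm(svm_m, va), va$labels,
                      svm_m$class_order)$overall_accuracy
  expect_lt(lda_acc, 65)     # centered XOR is linearly inseparable
  expect_gt(svm_acc, 90)
  expect_gt(svm_acc, lda_acc)
})

test_that("evaluate builds confusion counts, recalls and overall accuracy", {
  cls <- c("carrot", "purslane", "goosegrass", "humifuse")
  truth <- rep(cls, each = 3000)
  perfect <- evaluate(truth, truth, cls)
  expect_equal(perfect$overall_accuracy, 100)
  expect_equal(unname(perfect$per_class_accuracy), rep(100, 4))
  expect_true(all(perfect$confusion[row(perfect$confusion) !=
                                      col(perfect$confusion)] == 0))
  # one class fully misassigned: 0% there, 75% overall
  pred <- truth
  pred[truth == "purslane"] <- "carrot"
  r <- evaluate(pred, truth, cls)
  expect_equal(unname(r$per_class_accuracy["purslane"]), 0)
  expect_equal(r$overall_accuracy, 75)
  expect_equal(unname(rowSums(r$confusion)), rep(3000, 4))
  # balanced design: overall equals mean of per-class accuracies
  expect_equal(r$overall_accuracy, mean(r$per_class_accuracy))
  expect_error(evaluate(c("a"), c("a", "b"), c("a", "b")), "equal length")
  expect_error(evaluate(character(0), character(0), "a"), "empty")
  expect_error(evaluate(c("a", "z"), c("a", "a"), c("a", "b")), "unknown")
})
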