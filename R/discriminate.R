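# Multiclass Fisher discriminant analysis (first principles) and an
# RBF-kernel SVM (libsvm via e1071) with seeded grid-search tuning,
# plus shared accuracy reporting.

#' Fit a multiclass Fisher linear discriminant model
#'
#' Finds projection axes `w` maximizing the Fisher criterion
#' `J(w) = (w' Sb w) / (w' Sw w)` -- between-class scatter as large as
#' possible relative to within-class scatter. The generalized eigenproblem
#' is solved by whitening (Cholesky of `Sw`) followed by a symmetric
#' eigendecomposition; up to `min(d, g - 1)` axes are kept in decreasing
#' eigenvalue order, with a deterministic sign convention (largest-
#' magnitude loading positive). Class centers are stored in the projected
#' space for nearest-center classification.
#'
#' @param samples A [labeled_samples()] with at least 2 classes and
#'   nonsingular within-class scatter.
#' @param ridge Relative ridge added to the within-class scatter,
#'   `Sw + ridge * mean(diag(Sw)) * I`, before whitening. The default 0 is
#'   strict: singular `Sw` is an error. A small positive value (e.g.
#'   `1e-6`) regularizes exactly collinear feature sets, such as the full
#'   feature dimension of mean-normalized spectra (whose rows satisfy one
#'   exact linear constraint) or the full redundant wavelet expansion.
#' @return An object of class `lda_model`: `W` (d x m projection matrix),
#'   `projected_centers` (g x m), `eigenvalues`, `Sb`, `Sw`,
#'   `class_order`.
#' @export
fit_lda <- function(samples, ridge = 0) {
  st <- scatter_matrices(samples)
  if (ridge > 0)
    st$Sw <- st$Sw + ridge * mean(diag(st$Sw)) * diag(ncol(st$Sw))
  R <- tryCatch(chol(st$Sw), error = function(e) NULL)
  if (is.null(R) || any(diag(R) < 1e-10 * sqrt(max(diag(st$Sw)))))
    stop("singular within-class scatter; reduce the feature subset ",
         "(e.g. via stepwise_select) or drop duplicated features",
         call. = FALSE)
  d <- ncol(st$Sw)
  Rinv <- backsolve(R, diag(d))
  A <- t(Rinv) %*% st$Sb %*% Rinv
  A <- (A + t(A)) / 2
  eig <- eigen(A, symmetric = TRUE)
  m <- min(d, st$g - 1L)
  W <- Rinv %*% eig$vectors[, seq_len(m), drop = FALSE]
  # sign convention: largest-magnitude loading of each axis positive
  for (j in seq_len(m)) {
    i <- which.max(abs(W[, j]))
    if (W[i, j] < 0) W[, j] <- -W[, j]
  }
  centers <- st$class_means %*% W
  structure(list(W = W, projected_centers = centers,
                 eigenvalues = eig$values[seq_len(m)],
                 Sb = st$Sb, Sw = st$Sw,
                 class_order = rownames(st$class_means)),
            class = "lda_model")
}

#' Classify samples with a fitted LDA model
#'
#' Projects each sample through the discriminant axes and assigns the
#' class of the nearest projected center (Euclidean distance); exact ties
#' go to the earlier class in `class_order`.
#'
#' @param model A [fit_lda()] result.
#' @param samples Numeric matrix (`n x d`, matching the fit's feature
#'   width) or a [labeled_samples()].
#' @return Character vector of predicted class labels.
#' @export
predict_lda <- function(model, samples) {
  stopifnot(inherits(model, "lda_model"))
  X <- if (inherits(samples, "labeled_samples")) samples$spectra
       else as.matrix(samples)
  if (ncol(X) != nrow(model$W))
    stop("feature width (", ncol(X), ") does not match the model (",
         nrow(model$W), ")", call. = FALSE)
  P <- X %*% model$W
  C <- model$projected_centers
  # squared distances to every center
  d2 <- outer(rowSums(P^2), rep(1, nrow(C))) - 2 * P %*% t(C) +
    outer(rep(1, nrow(P)), rowSums(C^2))
  model$class_order[apply(d2, 1L, which.min)]   # which.min: first = earlier
}

#' RBF-SVM tuning specification
#'
#' Geometric C/gamma grids following the libsvm practical-guide
#' convention, with stratified cross-validation fold count and seed.
#'
#' @param C_grid,gamma_grid Strictly positive parameter grids.
#' @param cv_folds Number of stratified CV folds (default 5).
#' @param seed RNG seed controlling fold assignment.
#' @return An object of class `svm_spec`.
#' @export
svm_spec <- function(C_grid = 2^seq(-5, 15, by = 2),
                     gamma_grid = 2^seq(-15, 3, by = 2),
                     cv_folds = 5L, seed = 1L) {
  if (!length(C_grid) || !length(gamma_grid) ||
      any(C_grid <= 0) || any(gamma_grid <= 0))
    stop("C and gamma grids must be nonempty and strictly positive",
         call. = FALSE)
  structure(list(C_grid = C_grid, gamma_grid = gamma_grid,
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
            class = "svm_spec")
}

#' Tune and fit an RBF-kernel SVM by seeded grid search
#'
#' Computes stratified k-fold cross-validation accuracy on the training
#' samples for every `(C, gamma)` pair, picks the maximizer (ties to the
#' smaller C, then the smaller gamma), and refits on all training data.
#' Features are standardized to train-set mean 0 / variance 1 before the
#' RBF kernel (the scaling is stored and re-applied at prediction).
#'
#' @param samples A [labeled_samples()] with at least `cv_folds` samples
#'   per class.
#' @param spec An [svm_spec()].
#' @return An object of class `svm_model`: the fitted e1071 model,
#'   `chosen_C`, `chosen_gamma`, the full `cv_table`, the standardization
#'   (`center`, `scale`) and `class_order`.
#' @export
tune_and_fit_svm <- function(samples, spec = svm_spec()) {
  stopifnot(inherits(samples, "labeled_samples"),
            inherits(spec, "svm_spec"))
  X <- samples$spectra
  y <- factor(samples$labels, levels = unique(samples$labels))
  counts <- table(y)
  if (any(counts < spec$cv_folds))
    stop("every class needs at least `cv_folds` samples; deficient: ",
         paste(names(counts)[counts < spec$cv_folds], collapse = ", "),
         call. = FALSE)
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")

  # seeded stratified fold assignment
  set.seed(spec$seed)
  fold <- integer(nrow(Xs))
  for (k in levels(y)) {
    idx <- which(y == k)
    fold[idx] <- sample(rep_len(seq_len(spec$cv_folds), length(idx)))
  }

  grid <- expand.grid(C = spec$C_grid, gamma = spec$gamma_grid)
  acc <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    correct <- 0L
    for (f in seq_len(spec$cv_folds)) {
      tr <- fold != f
      fit <- e1071::svm(Xs[tr, , drop = FALSE], y[tr],
                        kernel = "radial", cost = grid$C[i],
                        gamma = grid$gamma[i], scale = FALSE)
      pred <- stats::predict(fit, Xs[!tr, , drop = FALSE])
      correct <- correct + sum(pred == y[!tr])
    }
    acc[i] <- correct / nrow(Xs)
  }
  # ties -> smaller C then smaller gamma (grid ordered C-fastest)
  ord <- order(-acc, grid$C, grid$gamma)
  best <- ord[1L]
  fit <- e1071::svm(Xs, y, kernel = "radial", cost = grid$C[best],
                    gamma = grid$gamma[best], scale = FALSE)
  structure(list(fit = fit, chosen_C = grid$C[best],
                 chosen_gamma = grid$gamma[best],
                 cv_table = cbind(grid, cv_accuracy = acc),
                 center = ctr, scale = scl,
                 class_order = levels(y)),
            class = "svm_model")
}

#' Classify samples with a fitted SVM model
#'
#' @param model A [tune_and_fit_svm()] result.
#' @param samples Numeric matrix or [labeled_samples()] with the fit's
#'   feature width.
#' @return Character vector of predicted class labels.
#' @export
predict_svm <- function(model, samples) {
  stopifnot(inherits(model, "svm_model"))
  X <- if (inherits(samples, "labeled_samples")) samples$spectra
       else as.matrix(samples)
  if (ncol(X) != length(model$center))
    stop("feature width does not match the model", call. = FALSE)
  Xs <- sweep(sweep(X, 2L, model$center), 2L, model$scale, "/")
  as.character(stats::predict(model$fit, Xs))
}

#' Confusion matrix and accuracy report
#'
#' Confusion counts (rows = truth, columns = prediction), per-class
#' recall in percent, and overall accuracy `100 * correct / total`. With
#' equal per-class validation counts the overall accuracy equals the mean
#' of the per-class accuracies.
#'
#' @param predictions,truth Equal-length label vectors.
#' @param class_order Class labels defining row/column order; every label
#'   in either vector must appear here.
#' @return An object of class `accuracy_report`: `confusion`,
#'   `per_class_accuracy` (named, %), `overall_accuracy` (%), `n`.
#' @export
evaluate <- function(predictions, truth, class_order) {
  predictions <- as.character(predictions); truth <- as.character(truth)
  if (length(predictions) != length(truth))
    stop("`predictions` and `truth` must have equal length", call. = FALSE)
  if (!length(truth)) stop("empty inputs", call. = FALSE)
  unknown <- setdiff(unique(c(predictions, truth)), class_order)
  if (length(unknown))
    stop("unknown label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  tf <- factor(truth, levels = class_order)
  pf <- factor(predictions, levels = class_order)
  conf <- table(truth = tf, prediction = pf)
  per_class <- 100 * diag(conf) / pmax(rowSums(conf), 1L)
  per_class[rowSums(conf) == 0] <- NA_real_
  structure(list(confusion = conf,
                 per_class_accuracy = per_class,
                 overall_accuracy = 100 * sum(diag(conf)) / length(truth),
                 n = length(truth)),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> overall %.1f%% (n = %d)\n",
              x$overall_accuracy, x$n))
  print(round(x$per_class_accuracy, 1))
  invisible(x)
}
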