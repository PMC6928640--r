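# End-to-end experiment: simulate -> preprocess -> features -> select ->
# train -> evaluate, reproducing the accuracy-vs-feature-count design for
# both feature types (raw bands vs wavelet coefficients) and both models
# (LDA vs RBF-SVM).

#' Experiment configuration
#'
#' @param scene A [scene_config()] describing the synthetic field.
#' @param n_images Number of acquisitions to simulate.
#' @param n_train_images,n_validation_images Sizes of the disjoint image
#'   splits (the emulated campaign design is 20/20 out of 41).
#' @param n_per_class Pixels sampled per class per role (design: 3000).
#' @param feature_types Subset of `c("bands", "wavelet")`.
#' @param feature_counts Numbers of selected features at which to
#'   evaluate; `NA` means the full feature dimension. Default `1:20` plus
#'   full.
#' @param models Subset of `c("lda", "svm")`.
#' @param svm An [svm_spec()] for the SVM arm.
#' @param F_enter,F_remove Stepwise-selection thresholds.
#' @param seed Master seed; all stage seeds derive from it.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(scene = scene_config(),
                              n_images = 41L,
                              n_train_images = 20L,
                              n_validation_images = 20L,
                              n_per_class = 3000L,
                              feature_types = c("bands", "wavelet"),
                              feature_counts = c(1:20, NA),
                              models = c("lda", "svm"),
                              svm = svm_spec(),
                              F_enter = 3.84, F_remove = 2.71,
                              seed = 1L) {
  feature_types <- match.arg(feature_types, c("bands", "wavelet"),
                             several.ok = TRUE)
  models <- match.arg(models, c("lda", "svm"), several.ok = TRUE)
  if (n_train_images + n_validation_images > n_images)
    stop("train + validation split sizes exceed `n_images`", call. = FALSE)
  structure(list(scene = scene, n_images = as.integer(n_images),
                 n_train_images = as.integer(n_train_images),
                 n_validation_images = as.integer(n_validation_images),
                 n_per_class = as.integer(n_per_class),
                 feature_types = feature_types,
                 feature_counts = feature_counts,
                 models = models, svm = svm,
                 F_enter = F_enter, F_remove = F_remove,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Run the full discrimination experiment
#'
#' Simulates an acquisition series, splits it into disjoint train and
#' validation image sets, samples labelled plant pixels, preprocesses
#' them (trim below 410 nm, average blocks of 4, mean-normalize), builds
#' band and/or wavelet feature tables, runs Wilks stepwise selection on
#' the training samples only, and evaluates each configured model at each
#' configured feature count on the validation samples only. Fully
#' deterministic given the config seed.
#'
#' @param config An [experiment_config()].
#' @return An object of class `experiment_report`: `results` (nested list
#'   `results[[feature_type]][[model]][[as.character(k)]]`, each an
#'   [evaluate()] report), `selection` (per feature type), `class_order`,
#'   `feature_counts_used`, and the `config`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 4L)

  series <- generate_acquisition_series(config$scene, config$n_images,
                                        seed = seeds[1L])
  ids <- vapply(series, function(s) s$cube$acquisition_id, character(1))
  set.seed(seeds[2L])
  shuffled <- sample(ids)
  train_ids <- shuffled[seq_len(config$n_train_images)]
  val_ids <- shuffled[config$n_train_images +
                        seq_len(config$n_validation_images)]

  roles <- sample_pixels(series, config$n_per_class, train_ids, val_ids,
                         seed = seeds[3L])
  prep <- function(s)
    normalize_samples(average_bands(trim_bands(s, 410), 4L))
  train_b <- prep(roles$train)
  val_b <- prep(roles$validation)
  class_order <- train_b$class_set

  feature_tables <- list()
  if ("bands" %in% config$feature_types)
    feature_tables$bands <- list(train = train_b, validation = val_b)
  if ("wavelet" %in% config$feature_types)
    feature_tables$wavelet <- list(train = coefficient_features(train_b),
                                   validation = coefficient_features(val_b))

  results <- list(); selection <- list()
  for (ft in names(feature_tables)) {
    tr <- feature_tables[[ft]]$train
    va <- feature_tables[[ft]]$validation
    d <- ncol(tr$spectra)
    ks <- unique(ifelse(is.na(config$feature_counts), d,
                        config$feature_counts))
    ks <- sort(ks[ks >= 1 & ks <= d])
    k_max <- max(ks[ks < d], 0L)
    sel <- if (k_max > 0L)
      stepwise_select(tr, max_features = k_max,
                      F_enter = config$F_enter, F_remove = config$F_remove)
    else NULL
    selection[[ft]] <- sel
    results[[ft]] <- list()
    for (mdl in config$models) results[[ft]][[mdl]] <- list()
    for (k in ks) {
      feats <- if (k == d) seq_len(d) else sel$selected[seq_len(k)]
      if (k != d && length(sel$selected) < k) next  # selection fell short
      sub <- function(s) labeled_samples(
        s$spectra[, feats, drop = FALSE], s$labels, s$image_ids,
        role = s$role, class_set = s$class_set)
      tr_k <- sub(tr); va_k <- sub(va)
      for (mdl in config$models) {
        # at the full dimension, mean normalization (and the redundant
        # wavelet expansion) make Sw exactly collinear; ridge-regularize
        pred <- if (mdl == "lda")
          predict_lda(fit_lda(tr_k, ridge = if (k == d) 1e-6 else 0), va_k)
        else
          predict_svm(tune_and_fit_svm(tr_k, config$svm), va_k)
        results[[ft]][[mdl]][[as.character(k)]] <-
          evaluate(pred, va_k$labels, class_order)
      }
    }
  }
  structure(list(results = results, selection = selection,
                 class_order = class_order,
                 train_images = sort(train_ids),
                 validation_images = sort(val_ids),
                 config = config),
            class = "experiment_report")
}

#' Accuracy table of one experiment arm
#'
#' @param report An [run_experiment()] report.
#' @param feature_type `"bands"` or `"wavelet"`.
#' @param model `"lda"` or `"svm"`.
#' @return Numeric matrix `(n_classes + 1) x n_k`: per-class accuracies
#'   and an `"overall"` row, in percent, columns named by feature count.
#' @export
accuracy_table <- function(report, feature_type, model) {
  stopifnot(inherits(report, "experiment_report"))
  arm <- report$results[[feature_type]][[model]]
  if (is.null(arm) || !length(arm))
    stop("report holds no ", feature_type, "/", model, " arm",
         call. = FALSE)
  out <- vapply(arm, function(r)
    c(r$per_class_accuracy, overall = r$overall_accuracy),
    numeric(length(report$class_order) + 1L))
  rownames(out) <- c(report$class_order, "overall")
  out
}

#' Pairwise accuracy differences between experiment arms
#'
#' Signed per-class (and overall) accuracy differences in percentage
#' points at each feature count: for `axis = "feature_type"`,
#' wavelet minus bands (per model); for `axis = "model"`, SVM minus LDA
#' (per feature type).
#'
#' @param report An [run_experiment()] report.
#' @param axis `"feature_type"` or `"model"`.
#' @param within The arm held fixed: the model name for
#'   `axis = "feature_type"` (default first configured model), the
#'   feature type for `axis = "model"` (default first configured type).
#' @return Numeric matrix `(n_classes + 1) x n_k` of differences.
#' @export
difference_table <- function(report, axis = c("feature_type", "model"),
                             within = NULL) {
  axis <- match.arg(axis)
  if (axis == "feature_type") {
    if (is.null(within)) within <- report$config$models[1L]
    a <- accuracy_table(report, "wavelet", within)
    b <- accuracy_table(report, "bands", within)
  } else {
    if (is.null(within)) within <- report$config$feature_types[1L]
    a <- accuracy_table(report, within, "svm")
    b <- accuracy_table(report, within, "lda")
  }
  ks <- intersect(colnames(a), colnames(b))
  if (!length(ks)) stop("arms share no feature counts", call. = FALSE)
  a[, ks, drop = FALSE] - b[, ks, drop = FALSE]
}

#' Format an accuracy table as text
#'
#' Rows = feature counts, columns = class x model, mirroring the layout
#' of a published accuracy table.
#'
#' @param report An [run_experiment()] report.
#' @param feature_type `"bands"` or `"wavelet"`.
#' @return Character vector of formatted lines, invisibly; printed.
#' @export
format_accuracy_text <- function(report, feature_type) {
  tabs <- lapply(report$config$models, function(m)
    accuracy_table(report, feature_type, m))
  names(tabs) <- report$config$models
  ks <- colnames(tabs[[1L]])
  hdr <- c("k", unlist(lapply(rownames(tabs[[1L]]), function(cl)
    paste(cl, toupper(names(tabs)), sep = "_"))))
  lines <- vapply(ks, function(k) {
    vals <- unlist(lapply(rownames(tabs[[1L]]), function(cl)
      vapply(tabs, function(t) sprintf("%.1f", t[cl, k]), character(1))))
    paste(c(k, vals), collapse = "\t")
  }, character(1))
  out <- c(paste(hdr, collapse = "\t"), lines)
  cat(out, sep = "\n")
  invisible(out)
}
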