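# Scatter-matrix separability and Wilks'-statistic stepwise feature
# selection. Determinants of scatter matrices are computed in log space
# via Cholesky factorization: on 80+ features the raw determinants
# overflow doubles long before the ratio |Sm|/|Sw| does.

#' Within-class and total scatter matrices of a labelled sample
#'
#' Deviation (scatter) matrices, unnormalized:
#' `Sw = sum_c sum_i (x_i - mean_c)(x_i - mean_c)'` over classes and
#' `Sm = sum_i (x_i - grand_mean)(x_i - grand_mean)'` over all samples,
#' restricted to `feature_subset`. `Sb = Sm - Sw` is the between-class
#' scatter.
#'
#' @param samples A [labeled_samples()] with at least 2 classes and at
#'   least 2 samples per class.
#' @param feature_subset Integer vector of distinct feature indices;
#'   default all features.
#' @return An object of class `scatter_stats`: `Sw`, `Sm`, `Sb`,
#'   `class_means` (class x feature matrix), `grand_mean`, `n_per_class`,
#'   `n`, `g`, and the `feature_subset` used.
#' @export
scatter_matrices <- function(samples, feature_subset = NULL) {
  stopifnot(inherits(samples, "labeled_samples"))
  X <- samples$spectra
  if (is.null(feature_subset)) feature_subset <- seq_len(ncol(X))
  if (anyDuplicated(feature_subset) ||
      any(feature_subset < 1L | feature_subset > ncol(X)))
    stop("`feature_subset` must be distinct, valid column indices",
         call. = FALSE)
  X <- X[, feature_subset, drop = FALSE]
  lab <- samples$labels
  cls <- unique(lab)
  if (length(cls) < 2L) stop("need at least 2 classes", call. = FALSE)
  counts <- table(factor(lab, levels = cls))
  if (any(counts < 2L))
    stop("every class needs at least 2 samples; deficient: ",
         paste(names(counts)[counts < 2L], collapse = ", "), call. = FALSE)
  grand <- colMeans(X)
  Sm <- crossprod(sweep(X, 2L, grand))
  Sw <- matrix(0, ncol(X), ncol(X))
  means <- matrix(0, length(cls), ncol(X),
                  dimnames = list(cls, colnames(X)))
  for (k in cls) {
    Xk <- X[lab == k, , drop = FALSE]
    mk <- colMeans(Xk)
    means[k, ] <- mk
    Sw <- Sw + crossprod(sweep(Xk, 2L, mk))
  }
  structure(list(Sw = Sw, Sm = Sm, Sb = Sm - Sw, class_means = means,
                 grand_mean = grand, n_per_class = as.integer(counts),
                 n = nrow(X), g = length(cls),
                 feature_subset = feature_subset),
            class = "scatter_stats")
}

# log-determinant of a symmetric PSD matrix; NA signals singularity
logdet_psd <- function(M) {
  R <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(R)) return(NA_real_)
  d <- diag(R)
  scale <- sqrt(max(diag(M), 1e-300))
  if (any(d < 1e-10 * scale)) return(NA_real_)
  2 * sum(log(d))
}

# Wilks Lambda = |Sw| / |Sm| for a feature subset, from full-data scatter
# matrices; NA when Sw (or Sm) is singular on that subset.
wilks_lambda_subset <- function(Sw_full, Sm_full, subset) {
  lw <- logdet_psd(Sw_full[subset, subset, drop = FALSE])
  lm <- logdet_psd(Sm_full[subset, subset, drop = FALSE])
  if (is.na(lw) || is.na(lm)) return(NA_real_)
  exp(lw - lm)
}

#' Scatter-matrix class separability J
#'
#' `J = |Sm| / |Sw|`, the determinant ratio of total to within-class
#' scatter; `J >= 1`, with equality when all class means coincide, and
#' `1/J` is Wilks' Lambda. Invariant to translation and to any common
#' invertible linear map of the features.
#'
#' @param stats A [scatter_matrices()] result.
#' @return The separability `J` (a single number).
#' @export
separability <- function(stats) {
  stopifnot(inherits(stats, "scatter_stats"))
  lw <- logdet_psd(stats$Sw)
  if (is.na(lw))
    stop("singular within-class scatter on features [",
         paste(stats$feature_subset, collapse = ", "),
         "]; reduce or deduplicate the subset", call. = FALSE)
  lm <- logdet_psd(stats$Sm)
  if (is.na(lm))
    stop("singular total scatter on features [",
         paste(stats$feature_subset, collapse = ", "), "]", call. = FALSE)
  exp(lm - lw)
}

#' Stepwise feature selection by Wilks' statistic
#'
#' Classical stepwise discriminant selection. At each forward step the
#' candidate feature maximizing the entry partial-F,
#' `F = ((n - g - p) / (g - 1)) * (1 - lambda) / lambda` with
#' `lambda = Lambda(selected + candidate) / Lambda(selected)` (`n`
#' samples, `g` classes, `p` currently selected features), enters if
#' `F > F_enter`; after each entry, any selected feature whose removal
#' partial-F falls below `F_remove` is removed (the just-entered feature
#' is exempt within its own step). Ties break to the lowest feature
#' index. Selection stops at `max_features` or when no candidate passes.
#'
#' @param samples A [labeled_samples()].
#' @param max_features Maximum number of features to select.
#' @param F_enter,F_remove Entry/removal thresholds
#'   (`F_enter >= F_remove`); defaults 3.84 / 2.71.
#' @param removal Set `FALSE` for pure forward selection.
#' @return An object of class `selection_result`: `selected` (ordered
#'   indices), `J_trace` and `wilks_trace` (after each step),
#'   `F_enter`/`F_remove`, and `step_log` (per-step data frame of
#'   candidate F statistics).
#' @export
stepwise_select <- function(samples, max_features,
                            F_enter = 3.84, F_remove = 2.71,
                            removal = TRUE) {
  stopifnot(inherits(samples, "labeled_samples"))
  d <- ncol(samples$spectra)
  if (max_features > d)
    stop("`max_features` exceeds the feature count", call. = FALSE)
  if (F_enter < F_remove)
    stop("`F_enter` must be >= `F_remove`", call. = FALSE)
  st <- scatter_matrices(samples)
  Sw <- st$Sw; Sm <- st$Sm; n <- st$n; g <- st$g

  partial_F <- function(lambda_ratio, p_after) {
    # p_after = |selected| counting the candidate under test
    ((n - g - p_after + 1) / (g - 1)) * (1 - lambda_ratio) / lambda_ratio
  }

  selected <- integer(0)
  lambda_cur <- 1
  J_trace <- numeric(0); wilks_trace <- numeric(0)
  step_log <- list()

  repeat {
    if (length(selected) >= max_features) break
    cand <- setdiff(seq_len(d), selected)
    lam_new <- vapply(cand, function(cc)
      wilks_lambda_subset(Sw, Sm, c(selected, cc)), numeric(1))
    ratio <- lam_new / lambda_cur
    Fs <- partial_F(ratio, length(selected) + 1L)
    Fs[is.na(lam_new)] <- NA_real_
    step_log[[length(step_log) + 1L]] <-
      data.frame(step = length(step_log) + 1L, feature = cand, F = Fs)
    ok <- which(!is.na(Fs) & Fs > F_enter)
    if (!length(ok)) {
      if (!length(selected))
        message("no candidate passed F_enter at step 1; empty selection")
      break
    }
    best <- ok[which.max(Fs[ok])]      # which.max -> first max: lowest index
    entered <- cand[best]
    selected <- c(selected, entered)
    lambda_cur <- lam_new[best]
    J_trace <- c(J_trace, 1 / lambda_cur)
    wilks_trace <- c(wilks_trace, lambda_cur)

    if (removal && length(selected) > 1L) {
      repeat {
        p <- length(selected)
        removable <- setdiff(selected, entered)
        if (!length(removable)) break
        F_rm <- vapply(removable, function(v) {
          lam_wo <- wilks_lambda_subset(Sw, Sm, setdiff(selected, v))
          if (is.na(lam_wo)) return(Inf)  # cannot assess; keep
          partial_F(lambda_cur / lam_wo, p)
        }, numeric(1))
        worst <- which.min(F_rm)
        if (F_rm[worst] >= F_remove) break
        v <- removable[worst]
        selected <- setdiff(selected, v)
        lambda_cur <- wilks_lambda_subset(Sw, Sm, selected)
        J_trace <- c(J_trace, 1 / lambda_cur)
        wilks_trace <- c(wilks_trace, lambda_cur)
      }
    }
  }
  structure(list(selected = selected, J_trace = J_trace,
                 wilks_trace = wilks_trace,
                 F_enter = F_enter, F_remove = F_remove,
                 step_log = do.call(rbind, step_log)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d feature(s): %s\n", length(x$selected),
              paste(x$selected, collapse = ", ")))
  if (length(x$J_trace))
    cat("final J =", format(x$J_trace[length(x$J_trace)]), "\n")
  invisible(x)
}

#' Exhaustive feature-subset search (test oracle)
#'
#' Scans all `choose(d, k)` subsets and returns the one maximizing the
#' separability `J`; subsets whose within-class scatter is singular are
#' skipped. Ties break lexicographically. Guarded by a subset-count cap.
#'
#' @param samples A [labeled_samples()].
#' @param k Subset size.
#' @param cap Maximum number of subsets to scan (default 20000).
#' @return Integer vector of `k` feature indices.
#' @export
exhaustive_select <- function(samples, k, cap = 20000L) {
  stopifnot(inherits(samples, "labeled_samples"))
  d <- ncol(samples$spectra)
  if (choose(d, k) > cap)
    stop("choose(d, k) exceeds the configured cap", call. = FALSE)
  st <- scatter_matrices(samples)
  subsets <- utils::combn(d, k)
  best <- NULL; best_J <- -Inf
  for (i in seq_len(ncol(subsets))) {
    s <- subsets[, i]
    lam <- wilks_lambda_subset(st$Sw, st$Sm, s)
    if (is.na(lam)) next
    J <- 1 / lam
    if (J > best_J) { best_J <- J; best <- s }  # strict: ties -> earliest
  }
  if (is.null(best))
    stop("every size-", k, " subset had singular within-class scatter",
         call. = FALSE)
  best
}

#' Serialize a selection result to JSON
#'
#' Records the selected indices (and their band-center wavelengths, when
#' the features are spectral bands, in selection order) plus the J and
#' Wilks traces.
#'
#' @param result A [stepwise_select()] result.
#' @param path Output JSON path.
#' @param wavelengths Optional feature wavelength table (nm).
#' @return `path`, invisibly.
#' @export
write_selection_json <- function(result, path, wavelengths = NULL) {
  stopifnot(inherits(result, "selection_result"))
  rec <- list(selected = result$selected,
              J_trace = result$J_trace,
              wilks_trace = result$wilks_trace,
              F_enter = result$F_enter, F_remove = result$F_remove)
  if (!is.null(wavelengths))
    rec$selected_wavelengths_nm <- wavelengths[result$selected]
  jsonlite::write_json(rec, path, digits = NA)
  invisible(path)
}
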