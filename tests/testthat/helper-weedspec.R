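# shared fixtures, all generated in code

# small, fast scene for pipeline-level tests
tiny_scene <- function(...) {
  scene_config(image_size = c(24L, 24L), patch_px = 6L, ...)
}

# labelled Gaussian class data: `means` is a classes x d matrix
gaussian_samples <- function(n_per_class, means, sd = 1, seed = 1,
                             role = "train") {
  set.seed(seed)
  g <- nrow(means); d <- ncol(means)
  X <- do.call(rbind, lapply(seq_len(g), function(k)
    matrix(stats::rnorm(n_per_class * d, sd = sd), n_per_class, d) +
      matrix(means[k, ], n_per_class, d, byrow = TRUE)))
  labs <- rep(rownames(means) %||% paste0("c", seq_len(g)),
              each = n_per_class)
  labeled_samples(X, labs, rep("imgX", length(labs)), role = role)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# XOR-family construction: two classes, each a pair of diagonal Gaussian
# blobs; linearly inseparable by design
xor_samples <- function(n_per_blob = 60, sep = 3, sd = 0.6, seed = 1,
                        role = "train") {
  set.seed(seed)
  blob <- function(cx, cy)
    cbind(stats::rnorm(n_per_blob, cx, sd), stats::rnorm(n_per_blob, cy, sd))
  X <- rbind(blob(-sep, -sep), blob(sep, sep),   # class a: main diagonal
             blob(-sep, sep), blob(sep, -sep))   # class b: anti-diagonal
  labeled_samples(X, rep(c("a", "b"), each = 2 * n_per_blob),
                  rep("imgX", 4 * n_per_blob), role = role)
}

# subset a labeled_samples to given feature columns
take_features <- function(s, idx) {
  labeled_samples(s$spectra[, idx, drop = FALSE], s$labels, s$image_ids,
                  role = s$role, class_set = s$class_set)
}
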