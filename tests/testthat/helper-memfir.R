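# Shared fixtures and independent oracles for the test suite.

# Welch-style band power oracle: integrates a smoothed periodogram over a
# frequency band. Independent of the package's filtering code.
welch_band_power <- function(x, fs, f1, f2) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), spans = c(11, 11),
                          taper = 0.1, plot = FALSE, detrend = TRUE)
  sel <- sp$freq >= f1 & sp$freq <= f2
  2 * sum(sp$spec[sel]) * diff(sp$freq[1:2])
}

# Small clip set covering all classes, deterministic in `seed`.
make_test_clips <- function(clips_per_class = 3L, seed = 1L,
                            n_samples = 4096L) {
  clips <- list()
  k <- 0L
  for (lb in c("normal", "interictal", "ictal")) {
    for (i in seq_len(clips_per_class)) {
      k <- k + 1L
      clips[[k]] <- generate_clip(lb, n_samples = n_samples,
                                  seed = seed * 10000L + k,
                                  clip_id = sprintf("%s_%02d", lb, i))
    }
  }
  clips
}

# Noise-free device model for exactness checks.
ideal_device <- function() device_model(program_sigma = 0, read_sigma_rel = 0)

# Linearly separable three-class biomarker-like dataset (blobs with
# arbitrary per-class feature means), for decoder sanity checks.
make_blob_dataset <- function(n_per_class = 100L, n_features = 20L,
                              seed = 1L, sd = 0.1) {
  set.seed(seed)
  mu <- matrix(stats::runif(3 * n_features), 3, n_features)
  X <- do.call(rbind, lapply(1:3, function(cl) {
    matrix(stats::rnorm(n_per_class * n_features, mean = mu[cl, ][col(
      matrix(0, n_per_class, n_features))], sd = sd),
      n_per_class, n_features)
  }))
  colnames(X) <- paste0("f", seq_len(n_features))
  out <- as.data.frame(X)
  out$label <- rep(c("normal", "interictal", "ictal"), each = n_per_class)
  out$source <- "S"
  out
}
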