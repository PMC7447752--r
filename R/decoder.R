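# Biomarker extraction, voltage normalization, the 21x3 perceptron decoder,
# and its crossbar implementation.

FEATURE_STATS <- c("max", "min", "mean", "abssum", "energy")

#' Extract the 20 biomarkers from four band-filtered waveforms
#'
#' Per band (delta, theta, alpha, beta, in that order), five statistics are
#' computed over the filtered waveform: maximum, minimum, mean, sum of
#' absolute values and sum of energy (sum of squares). Features are ordered
#' band-major (the delta block first).
#'
#' @param waveforms Matrix with one column per band (any number of rows
#'   >= 1), e.g. from [apply_bank_reference()] or
#'   [filter_signal_crossbar()].
#' @param label Optional class label attached as an attribute.
#' @param source `"S"` for software-filtered input, `"M"` for
#'   crossbar-filtered input.
#' @return Named numeric vector of length `5 * ncol(waveforms)` with
#'   attributes `label` and `source`.
#' @export
extract_biomarkers <- function(waveforms, label = NULL, source = c("S", "M")) {
  source <- match.arg(source)
  waveforms <- as.matrix(waveforms)
  if (nrow(waveforms) < 1L) stop_memfir("empty waveform")
  assert_finite(waveforms, "waveform values")
  bands <- colnames(waveforms) %||% paste0("band", seq_len(ncol(waveforms)))
  feats <- unlist(lapply(seq_len(ncol(waveforms)), function(m) {
    w <- waveforms[, m]
    v <- c(max(w), min(w), mean(w), sum(abs(w)), sum(w^2))
    names(v) <- paste(bands[m], FEATURE_STATS, sep = "_")
    v
  }))
  attr(feats, "label") <- label
  attr(feats, "source") <- source
  feats
}

#' Assemble biomarker vectors into a dataset
#'
#' @param feature_list List of vectors from [extract_biomarkers()].
#' @return Data frame with one feature column per biomarker plus `label`
#'   and `source` columns.
#' @export
biomarker_dataset <- function(feature_list) {
  feats <- do.call(rbind, lapply(feature_list, as.numeric))
  colnames(feats) <- names(feature_list[[1]])
  out <- as.data.frame(feats)
  out$label <- vapply(feature_list, function(f) as.character(attr(f, "label")),
                      character(1))
  out$source <- vapply(feature_list, function(f) attr(f, "source"), character(1))
  out
}

feature_columns <- function(data) {
  setdiff(colnames(data), c("label", "source"))
}

#' Fit the biomarker-to-voltage normalizer
#'
#' Per-feature linear transform `y = a * x + b` mapping the training
#' minimum to 0.1 V and the training maximum to 0.3 V (min-max convention).
#' A degenerate constant feature maps to the mid-range 0.2 V.
#'
#' @param train Data frame or matrix of training biomarkers (feature
#'   columns only, or a dataset from [biomarker_dataset()]).
#' @param v_lo,v_hi Target voltage range in V (defaults 0.1 and 0.3).
#' @return A `memfir_normalizer`: per-feature `a`, `b` and the range.
#' @export
fit_normalizer <- function(train, v_lo = 0.1, v_hi = 0.3) {
  if (is.data.frame(train)) train <- as.matrix(train[, feature_columns(train)])
  if (nrow(train) == 0L) stop_memfir("empty training set")
  lo <- apply(train, 2, min)
  hi <- apply(train, 2, max)
  rng <- hi - lo
  a <- ifelse(rng > 0, (v_hi - v_lo) / rng, 0)
  b <- ifelse(rng > 0, v_lo - a * lo, (v_lo + v_hi) / 2)
  structure(list(a = a, b = b, v_lo = v_lo, v_hi = v_hi),
            class = "memfir_normalizer")
}

#' Apply a fitted normalizer, clipping to the voltage bounds
#'
#' Values outside the training range (possible on test data) are clipped to
#' `[v_lo, v_hi]`, respecting the hardware read-voltage window.
#'
#' @param norm A `memfir_normalizer`.
#' @param x Data frame or matrix of biomarkers.
#' @return Matrix of input voltages in `[v_lo, v_hi]`.
#' @export
apply_normalizer <- function(norm, x) {
  if (is.data.frame(x)) x <- as.matrix(x[, feature_columns(x)])
  v <- sweep(sweep(x, 2, norm$a, "*"), 2, norm$b, "+")
  pmin(pmax(v, norm$v_lo), norm$v_hi)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Stratified train/test partition: within each class, a seeded shuffle and a
# floor(split * n_class) training share.
split_stratified <- function(labels, split = 0.7, seed = NULL) {
  with_seed(seed, {
    train <- integer(0)
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- sample(idx)
      train <- c(train, idx[seq_len(floor(split * length(idx)))])
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(labels), train))
  })
}

#' Train the single-layer perceptron decoder
#'
#' A 21 x 3 single-layer perceptron: 20 normalized biomarker voltages plus a
#' fixed bias input (`v_bias`, default 0.3 V) feed three sigmoid output
#' neurons, one per brain state. Weights are trained by full-batch gradient
#' descent on the mean squared error against one-hot targets (the gradient
#' is averaged over the batch, so the step size does not depend on the
#' dataset size; the default learning rate compensates for the narrow
#' 0.1-0.3 V input scale). The voltage normalizer is fitted on the training
#' split only. The data are split 70/30 stratified by class, so a balanced
#' 1800-sample dataset yields 1260 training and 540 testing rows.
#'
#' @param data Dataset from [biomarker_dataset()] (feature columns plus
#'   `label`).
#' @param split Training fraction (default 0.7).
#' @param seed Seed controlling the shuffle and the weight initialization.
#' @param lr Learning rate on the batch-averaged gradient (default 25).
#' @param epochs Training epochs (default 2000).
#' @param v_bias Bias input voltage in V (default 0.3).
#' @param classes Class order for the output neurons; defaults to
#'   normal/interictal/ictal when those labels are present.
#' @param indices Optional precomputed list with `train` and `test` index
#'   vectors (overrides `split`/`seed` for the partition), used to evaluate
#'   two filtering paths on identical partitions.
#' @return A `memfir_perceptron` with weights `W` (21 x 3), the fitted
#'   `normalizer`, `classes`, train/test accuracy and the index partition.
#' @export
train_perceptron <- function(data, split = 0.7, seed = NULL, lr = 25,
                             epochs = 2000L, v_bias = 0.3, classes = NULL,
                             indices = NULL) {
  labels <- as.character(data$label)
  if (is.null(classes)) {
    classes <- if (all(sort(unique(labels)) == sort(CLASS_LABELS))) {
      CLASS_LABELS
    } else sort(unique(labels))
  }
  if (length(classes) < 2L) stop_memfir("need at least two classes")
  if (is.null(indices)) {
    indices <- split_stratified(labels, split, derive_seed(seed, "split"))
  }
  if (!all(classes %in% labels[indices$train])) {
    stop_memfir("a class is missing from the training split")
  }
  feats <- as.matrix(data[, feature_columns(data)])
  norm <- fit_normalizer(feats[indices$train, , drop = FALSE])
  X <- cbind(apply_normalizer(norm, feats), bias = v_bias)
  Tmat <- 1 * outer(labels, classes, "==")
  Xtr <- X[indices$train, , drop = FALSE]
  Ttr <- Tmat[indices$train, , drop = FALSE]
  W <- with_seed(derive_seed(seed, "init"),
                 matrix(rnorm(ncol(X) * length(classes), 0, 0.1),
                        ncol(X), length(classes)))
  for (e in seq_len(epochs)) {
    A <- sigmoid(Xtr %*% W)
    delta <- (A - Ttr) * A * (1 - A)
    W <- W - (lr / nrow(Xtr)) * crossprod(Xtr, delta)
  }
  dimnames(W) <- list(c(colnames(feats), "bias"), classes)
  pred <- classes[max.col(X %*% W, ties.method = "first")]
  model <- structure(
    list(W = W, normalizer = norm, classes = classes, v_bias = v_bias,
         lr = lr, epochs = epochs, indices = indices,
         train_accuracy = mean(pred[indices$train] == labels[indices$train]),
         test_accuracy = mean(pred[indices$test] == labels[indices$test]),
         n_train = length(indices$train), n_test = length(indices$test)),
    class = "memfir_perceptron"
  )
  model
}

#' @export
print.memfir_perceptron <- function(x, ...) {
  cat(sprintf("<memfir_perceptron> %d x %d (%s)\n", nrow(x$W), ncol(x$W),
              paste(x$classes, collapse = "/")))
  cat(sprintf("  train accuracy %.2f%% (n = %d), test accuracy %.2f%% (n = %d)\n",
              100 * x$train_accuracy, x$n_train,
              100 * x$test_accuracy, x$n_test))
  cat(sprintf("  lr %.3g, %d epochs, bias input %.2g V; %d devices when mapped\n",
              x$lr, x$epochs, x$v_bias, device_count(x)))
  invisible(x)
}

#' @export
coef.memfir_perceptron <- function(object, ...) object$W

#' @export
summary.memfir_perceptron <- function(object, ...) {
  print(object)
  cat("  weight range [", signif(min(object$W), 4), ", ",
      signif(max(object$W), 4), "]\n", sep = "")
  invisible(object)
}

#' Predict brain states from raw biomarkers
#'
#' @param object A `memfir_perceptron`.
#' @param newdata Data frame or matrix of 20 biomarker columns.
#' @param type `"class"` (labels), `"prob"` (sigmoid activations) or
#'   `"voltage"` (the normalized 21-column input voltage matrix).
#' @param ... Unused.
#' @export
predict.memfir_perceptron <- function(object, newdata,
                                      type = c("class", "prob", "voltage"),
                                      ...) {
  type <- match.arg(type)
  X <- cbind(apply_normalizer(object$normalizer, newdata), bias = object$v_bias)
  if (type == "voltage") return(X)
  A <- sigmoid(X %*% object$W)
  colnames(A) <- object$classes
  if (type == "prob") return(A)
  object$classes[max.col(A, ties.method = "first")]
}

#' Map trained perceptron weights onto a crossbar
#'
#' The 21 x 3 weight matrix becomes 63 differential synapses, i.e. 126
#' devices.
#'
#' @param model A trained `memfir_perceptron`.
#' @param dm A [device_model()].
#' @return A `memfir_pair`.
#' @export
map_perceptron_to_crossbar <- function(model, dm = device_model()) {
  stopifnot(inherits(model, "memfir_perceptron"))
  map_to_conductance(model$W, dm)
}

#' Classify input-voltage vectors by software or crossbar inference
#'
#' Software path: label of the largest sigmoid activation. Crossbar path:
#' the 21-entry voltage vector is applied to the weight array and the label
#' of the output neuron with the largest current wins. Ties break to the
#' lowest class index. With noise disabled the two paths make identical
#' decisions (sigmoid is monotone).
#'
#' @param voltages Numeric vector of 21 input volts, or a matrix with one
#'   row per sample.
#' @param object A `memfir_perceptron` (software) or `memfir_pair`
#'   (crossbar) from [map_perceptron_to_crossbar()].
#' @param classes Class labels for the output columns (required for a bare
#'   pair without column names).
#' @param dm Device model for the crossbar path.
#' @param seed Optional read-noise seed.
#' @param read_noise Apply read noise on the crossbar path (default `TRUE`).
#' @param v_max Overvoltage bound for the decoder array in V (default
#'   0.3 V, the top of the biomarker voltage window; the decoder array is
#'   read at 0.1-0.3 V rather than the filter array's 0.2 V ceiling).
#' @return Character vector of predicted labels.
#' @export
classify <- function(voltages, object, classes = NULL, dm = NULL, seed = NULL,
                     read_noise = TRUE, v_max = 0.3) {
  V <- if (is.null(dim(voltages))) matrix(voltages, nrow = 1) else as.matrix(voltages)
  if (inherits(object, "memfir_perceptron")) {
    if (ncol(V) != nrow(object$W)) {
      stop_memfir("expected ", nrow(object$W), " input voltages, got ", ncol(V))
    }
    scores <- V %*% object$W
    classes <- object$classes
  } else if (inherits(object, "memfir_pair")) {
    if (ncol(V) != nrow(object$G_pos)) {
      stop_memfir("expected ", nrow(object$G_pos), " input voltages, got ", ncol(V))
    }
    if (is.null(dm)) dm <- object$device_model
    if (max(abs(V)) > v_max * (1 + 1e-12)) {
      stop_memfir("input voltages exceed the decoder read window (", v_max, " V)")
    }
    Gd <- object$G_pos - object$G_neg
    scores <- V %*% Gd
    if (read_noise && dm$read_sigma_rel > 0) {
      sd_I <- dm$read_sigma_rel *
        sqrt(V^2 %*% (object$G_pos^2 + object$G_neg^2))
      scores <- scores + with_seed(seed, rnorm(length(scores))) * sd_I
    }
    if (is.null(classes)) classes <- colnames(object$G_pos)
    if (is.null(classes)) stop_memfir("classes must be given for a bare pair")
  } else {
    stop_memfir("object must be a memfir_perceptron or memfir_pair")
  }
  classes[max.col(scores, ties.method = "first")]
}

#' Evaluate the S.S. / M.S. / M.M. operating modes
#'
#' Builds the two biomarker datasets from a set of clips — dataset S via the
#' software reference filter and dataset M via the (noisy) crossbar filter —
#' then repeats training/evaluation over `n_trials` seeded trials:
#' \itemize{
#'   \item S.S.: perceptron trained and evaluated on S (software inference);
#'   \item M.S.: perceptron trained and evaluated on M (software inference);
#'   \item M.M.: the M-trained perceptron mapped onto a crossbar
#'     (programming noise) and evaluated on M by argmax output current
#'     (read noise).
#' }
#' Within a trial, S and M share the same stratified 70/30 partition.
#'
#' @param clips List of `memfir_clip` objects covering all classes.
#' @param dm A [device_model()].
#' @param bank A `memfir_bank` (default: the four standard bands at the
#'   clips' sampling rate).
#' @param n_trials Number of trials (default 10; at least 2 for a standard
#'   deviation).
#' @param seed Master seed; every stage derives its own sub-seed.
#' @param lr,epochs,split Training parameters, as in [train_perceptron()].
#' @param read_noise,program_noise Enable the respective non-idealities for
#'   the M pathway (both default `TRUE`).
#' @return A `memfir_modes`: `table` (data frame: mode, mean, sd),
#'   `accuracy` (trials x modes matrix), and the `datasets` list
#'   (S and M data frames) invisibly reusable.
#' @export
evaluate_modes <- function(clips, dm = device_model(), bank = NULL,
                           n_trials = 10L, seed = 1L, lr = 25, epochs = 2000L,
                           split = 0.7, read_noise = TRUE,
                           program_noise = TRUE) {
  if (n_trials < 2L) stop_memfir("need at least 2 trials for a standard deviation")
  labels <- vapply(clips, function(c) c$label, character(1))
  if (length(unique(labels)) < 2L) stop_memfir("clips must cover multiple classes")
  if (is.null(bank)) bank <- build_filter_bank(default_band_specs(fs = clips[[1]]$fs))
  ds <- build_datasets(clips, bank, dm, seed = derive_seed(seed, "datasets"),
                       read_noise = read_noise, program_noise = program_noise)
  modes <- c("S.S.", "M.S.", "M.M.")
  acc <- matrix(NA_real_, n_trials, 3, dimnames = list(NULL, modes))
  for (t in seq_len(n_trials)) {
    tseed <- derive_seed(seed, "trial", t)
    idx <- split_stratified(ds$S$label, split, derive_seed(tseed, "split"))
    model_S <- train_perceptron(ds$S, seed = tseed, lr = lr, epochs = epochs,
                                indices = idx)
    model_M <- train_perceptron(ds$M, seed = tseed, lr = lr, epochs = epochs,
                                indices = idx)
    acc[t, "S.S."] <- model_S$test_accuracy
    acc[t, "M.S."] <- model_M$test_accuracy
    # M.M.: weights written to the array, inference by output current
    pair <- map_perceptron_to_crossbar(model_M, dm)
    if (program_noise) {
      pair <- program_pair(pair, dm, seed = derive_seed(tseed, "program"))
    }
    Xtest <- predict(model_M, ds$M[idx$test, ], type = "voltage")
    pred <- classify(Xtest, pair, classes = model_M$classes, dm = dm,
                     seed = derive_seed(tseed, "read"),
                     read_noise = read_noise)
    acc[t, "M.M."] <- mean(pred == ds$M$label[idx$test])
  }
  structure(
    list(
      table = data.frame(mode = modes, mean = colMeans(acc),
                         sd = apply(acc, 2, sd), row.names = NULL),
      accuracy = acc,
      n_trials = n_trials,
      datasets = ds
    ),
    class = "memfir_modes"
  )
}

#' @export
print.memfir_modes <- function(x, ...) {
  cat(sprintf("<memfir_modes> %d trials\n", x$n_trials))
  for (i in seq_len(nrow(x$table))) {
    cat(sprintf("  %-5s %.2f%% +/- %.2f%%\n", x$table$mode[i],
                100 * x$table$mean[i], 100 * x$table$sd[i]))
  }
  invisible(x)
}

#' Build the S (software-filtered) and M (crossbar-filtered) datasets
#'
#' Segments every clip into 600-sample windows, converts them to voltage
#' traces with one dataset-wide gain (largest absolute sample maps to
#' `v_read_max`), filters each trace through the software reference and
#' through the programmed crossbar, and extracts the 20 biomarkers from
#' both filtered outputs.
#'
#' @inheritParams evaluate_modes
#' @param seed Seed for programming and read noise.
#' @return List with data frames `S` and `M`, the programmed `pair`, the
#'   voltage `gain`, and `n_discarded` total samples dropped by
#'   segmentation.
#' @export
build_datasets <- function(clips, bank, dm = device_model(), seed = NULL,
                           read_noise = TRUE, program_noise = TRUE) {
  pair <- map_to_conductance(unclass(bank), dm)
  if (program_noise) {
    pair <- program_pair(pair, dm, seed = derive_seed(seed, "program"))
  }
  gmax <- max(vapply(clips, function(cl) max(abs(cl$samples)), numeric(1)))
  gain <- dm$v_read_max / gmax
  feats_S <- list()
  feats_M <- list()
  n_disc <- 0L
  k <- 0L
  for (cl in clips) {
    segs <- segment_clip(cl)
    n_disc <- n_disc + attr(segs, "discarded")
    for (sg in segs) {
      k <- k + 1L
      tr <- to_voltage(sg, v_read_max = dm$v_read_max, gain = gain)
      ref <- apply_bank_reference(tr$volts, bank)
      mes <- filter_signal_crossbar(tr, pair, dm,
                                    seed = derive_seed(seed, "read", k),
                                    read_noise = read_noise)
      feats_S[[k]] <- extract_biomarkers(ref, label = sg$label, source = "S")
      feats_M[[k]] <- extract_biomarkers(mes, label = sg$label, source = "M")
    }
  }
  list(S = biomarker_dataset(feats_S), M = biomarker_dataset(feats_M),
       pair = pair, gain = gain, n_discarded = n_disc)
}
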