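# Biomarker extraction, voltage normalization, perceptron training and the
# crossbar decoder path.

test_that("biomarkers reproduce closed-form values and a streaming oracle", {
  w1 <- matrix(2, 3, 1, dimnames = list(NULL, "delta"))
  f1 <- extract_biomarkers(w1)
  expect_equal(unname(as.numeric(f1)), c(2, 2, 2, 6, 12))

  w2 <- matrix(c(1, -1), 2, 1, dimnames = list(NULL, "delta"))
  expect_equal(unname(as.numeric(extract_biomarkers(w2))), c(1, -1, 0, 2, 2))

  set.seed(4)
  w <- matrix(rnorm(2400), 600, 4,
              dimnames = list(NULL, c("delta", "theta", "alpha", "beta")))
  got <- as.numeric(extract_biomarkers(w))
  # independent single-pass streaming recomputation
  oracle <- c()
  for (m in 1:4) {
    mx <- -Inf; mn <- Inf; s <- 0; sa <- 0; se <- 0
    for (i in 1:600) {
      v <- w[i, m]
      if (v > mx) mx <- v
      if (v < mn) mn <- v
      s <- s + v; sa <- sa + abs(v); se <- se + v * v
    }
    oracle <- c(oracle, mx, mn, s / 600, sa, se)
  }
  expect_lt(max(abs(got - oracle)), 1e-12)

  # permutation invariance of every statistic
  wp <- w[sample(600), , drop = FALSE]
  colnames(wp) <- colnames(w)
  expect_equal(as.numeric(extract_biomarkers(wp)), got, tolerance = 1e-12)

  expect_equal(length(as.numeric(extract_biomarkers(w))), 20L)
  expect_error(extract_biomarkers(w[0, , drop = FALSE]), "empty")
})

test_that("the min-max normalizer maps the training range onto 0.1-0.3 V", {
  train <- cbind(a = c(0, 10, 5), b = c(3, 3, 3))
  norm <- fit_normalizer(train)
  expect_equal(unname(norm$a["a"]), 0.02)
  expect_equal(unname(norm$b["a"]), 0.1)
  v <- apply_normalizer(norm, cbind(a = 5, b = 3))
  expect_equal(unname(v[1, "a"]), 0.2)
  expect_equal(unname(v[1, "b"]), 0.2)  # degenerate constant feature

  vt <- apply_normalizer(norm, train)
  expect_true(all(vt >= 0.1 & vt <= 0.3))
  # out-of-range test values are clipped to the hardware window
  vo <- apply_normalizer(norm, cbind(a = c(-5, 20), b = c(0, 9)))
  expect_true(all(vo >= 0.1 & vo <= 0.3))
  expect_error(fit_normalizer(train[0, , drop = FALSE]), "empty")
})

test_that("a balanced 1800-row dataset splits into 1260 training and 540 test rows", {
  labels <- rep(c("normal", "interictal", "ictal"), each = 600)
  idx <- memfir:::split_stratified(labels, 0.7, seed = 3)
  expect_length(idx$train, 1260L)
  expect_length(idx$test, 540L)
  expect_true(all(table(labels[idx$test]) == 180))
  expect_true(all(table(labels[idx$train]) == 420))
})

test_that("the perceptron separates linearly separable classes and is seed-stable", {
  blobs <- make_blob_dataset(n_per_class = 100, seed = 2)
  m1 <- train_perceptron(blobs, seed = 11)
  expect_gte(m1$test_accuracy, 0.95)
  m2 <- train_perceptron(blobs, seed = 11)
  expect_identical(m1$W, m2$W)
  m3 <- train_perceptron(blobs, seed = 12)
  expect_false(identical(m1$W, m3$W))
  expect_equal(dim(m1$W), c(21L, 3L))
  expect_equal(m1$n_train + m1$n_test, 300L)
})

test_that("weight mapping uses 126 devices and reconstructs the weights", {
  blobs <- make_blob_dataset(n_per_class = 30, seed = 5)
  model <- train_perceptron(blobs, seed = 1, epochs = 50)
  pair <- map_perceptron_to_crossbar(model, ideal_device())
  expect_equal(device_count(pair), 126L)
  expect_lt(max(abs(reconstruct_target(pair) - model$W)) / max(abs(model$W)),
            1e-12)

  # zero weight -> equal conductances
  model0 <- model
  model0$W[3, 2] <- 0
  p0 <- map_perceptron_to_crossbar(model0, ideal_device())
  expect_equal(p0$G_pos[3, 2], p0$G_neg[3, 2])
})

test_that("crossbar argmax equals software argmax without noise, with first-index ties", {
  blobs <- make_blob_dataset(n_per_class = 60, seed = 7)
  dm <- ideal_device()
  model <- train_perceptron(blobs, seed = 3)
  pair <- map_perceptron_to_crossbar(model, dm)
  X <- predict(model, blobs[model$indices$test, ], type = "voltage")
  soft <- classify(X, model)
  hard <- classify(X, pair, classes = model$classes, dm = dm,
                   read_noise = FALSE)
  expect_identical(soft, hard)

  # tie-breaking: equal currents resolve to the first class
  tie_pair <- map_to_conductance(matrix(1, 21, 3), dm)
  tied <- classify(rep(0.1, 21), tie_pair, classes = c("normal", "interictal", "ictal"),
                   dm = dm, read_noise = FALSE)
  expect_identical(tied, "normal")

  expect_error(classify(rep(0.1, 20), model), "21")
})

test_that("with all non-idealities off the three modes agree exactly", {
  clips <- make_test_clips(clips_per_class = 3L, seed = 21)
  res <- evaluate_modes(clips, dm = ideal_device(), n_trials = 2, seed = 4,
                        epochs = 300)
  expect_equal(res$accuracy[, "S.S."], res$accuracy[, "M.S."])
  expect_equal(res$accuracy[, "M.S."], res$accuracy[, "M.M."])
  expect_equal(nrow(res$accuracy), 2L)
  expect_error(evaluate_modes(clips, n_trials = 1), "at least 2")
})

test_that("mode evaluation returns one accuracy per trial and honours seeds", {
  clips <- make_test_clips(clips_per_class = 2L, seed = 31)
  r1 <- evaluate_modes(clips, n_trials = 3, seed = 9, epochs = 100)
  r2 <- evaluate_modes(clips, n_trials = 3, seed = 9, epochs = 100)
  expect_identical(r1$accuracy, r2$accuracy)
  expect_equal(dim(r1$accuracy), c(3L, 3L))
  expect_equal(r1$table$mean, unname(colMeans(r1$accuracy)))
})
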