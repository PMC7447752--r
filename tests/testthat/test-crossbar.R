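# Differential conductance mapping, programming/read noise, and the analog
# matrix-vector readout.

test_that("conductance mapping spans the device range and reconstructs exactly", {
  dm <- ideal_device()
  target <- matrix(c(0, 0.5, -1, 0.25), 2, 2)
  pair <- map_to_conductance(target, dm)
  # zero entry: both devices at the base conductance
  expect_equal(pair$G_pos[1, 1], 2)
  expect_equal(pair$G_neg[1, 1], 2)
  # the max-|value| entry saturates one side at g_max
  expect_equal(pair$G_neg[1, 2], 20)
  expect_true(all(pair$G_pos >= 2 & pair$G_pos <= 20))
  expect_lt(max(abs(reconstruct_target(pair) - target)), 1e-12)
  expect_error(map_to_conductance(matrix(c(1, NA), 1, 2)), "non-finite")
})

test_that("programming error has the injected spread and respects the bounds", {
  dm <- device_model(program_sigma = 0)
  pair <- map_to_conductance(matrix(runif(100, -1, 1), 10, 10), dm)
  expect_identical(program_pair(pair, dm, seed = 1)[c("G_pos", "G_neg")],
                   pair[c("G_pos", "G_neg")])

  # Monte-Carlo recovery of the injected std on mid-range devices
  dm2 <- device_model(program_sigma = 0.5)
  target <- matrix(seq(-0.5, 0.5, length.out = 5000), 50, 100)
  p0 <- map_to_conductance(target, dm2)
  p1 <- program_pair(p0, dm2, seed = 99)
  dev <- c(p1$G_pos - p0$G_pos, p1$G_neg - p0$G_neg)
  keep <- c(p1$G_pos, p1$G_neg) > dm2$g_min & c(p1$G_pos, p1$G_neg) < dm2$g_max
  expect_lt(abs(sd(dev[keep]) - 0.5) / 0.5, 0.05)
  expect_true(all(c(p1$G_pos, p1$G_neg) >= dm2$g_min))
  expect_true(all(c(p1$G_pos, p1$G_neg) <= dm2$g_max))

  # a device at g_max stays there under clipping
  hi <- map_to_conductance(matrix(1), dm2)
  expect_equal(hi$G_pos[1, 1], 20)
  many <- replicate(50, program_pair(hi, dm2, seed = NULL)$G_pos[1, 1])
  expect_true(all(many <= 20))
})

test_that("read_mvm implements Ohm's-law current summation exactly", {
  dm <- ideal_device()
  set.seed(31)
  target <- matrix(rnorm(121 * 4), 121, 4)
  pair <- map_to_conductance(target, dm)
  V <- runif(121, -0.2, 0.2)
  I <- read_mvm(V, pair, dm, read_noise = FALSE)
  # brute-force elementwise sum-of-products oracle
  oracle <- numeric(4)
  for (m in 1:4) {
    s <- 0
    for (k in 1:121) s <- s + V[k] * (pair$G_pos[k, m] - pair$G_neg[k, m])
    oracle[m] <- s
  }
  expect_lt(max(abs(I - oracle)) / max(abs(oracle)), 1e-12)
  expect_equal(read_mvm(numeric(121), pair, dm, read_noise = FALSE), numeric(4))

  # linearity and superposition with noise off
  V2 <- runif(121, -0.1, 0.1)
  expect_equal(read_mvm(0.5 * V, pair, dm, read_noise = FALSE), 0.5 * I,
               tolerance = 1e-12)
  expect_equal(read_mvm(0.5 * V + V2 * 0.5, pair, dm, read_noise = FALSE),
               0.5 * I + read_mvm(V2 * 0.5, pair, dm, read_noise = FALSE),
               tolerance = 1e-12)

  expect_error(read_mvm(numeric(120), pair, dm), "does not match")
  expect_error(read_mvm(rep(0.5, 121), pair, dm), "v_read_max")
})

test_that("noise-free crossbar filtering equals the software reference", {
  dm <- ideal_device()
  bank <- build_filter_bank()
  pair <- map_to_conductance(unclass(bank), dm)
  seg <- segment_clip(generate_clip("interictal", seed = 6))[[1]]
  tr <- to_voltage(seg)
  out <- filter_signal_crossbar(tr, pair, dm, read_noise = FALSE)
  ref <- apply_bank_reference(tr$volts, bank)
  expect_lt(max(abs(out - ref)) / max(abs(ref)), 1e-9)

  zero <- to_voltage(numeric(600), gain = 1, fs = 173.61)
  expect_equal(unname(filter_signal_crossbar(zero, pair, dm)[, ]),
               matrix(0, 600, 4))
})

test_that("noisy filtering and programming are reproducible under a fixed seed", {
  dm <- device_model()
  bank <- build_filter_bank()
  pair <- program_pair(map_to_conductance(unclass(bank), dm), dm, seed = 5)
  pair2 <- program_pair(map_to_conductance(unclass(bank), dm), dm, seed = 5)
  expect_identical(pair$G_pos, pair2$G_pos)

  tr <- to_voltage(segment_clip(generate_clip("ictal", seed = 8))[[1]])
  a <- filter_signal_crossbar(tr, pair, dm, seed = 17)
  b <- filter_signal_crossbar(tr, pair, dm, seed = 17)
  expect_identical(a, b)
  c <- filter_signal_crossbar(tr, pair, dm, seed = 18)
  expect_false(identical(a, c))
})

test_that("error statistics recover known offsets and injected noise", {
  ref <- matrix(rnorm(1200), 600, 2, dimnames = list(NULL, c("a", "b")))
  es0 <- error_stats(ref, ref)
  expect_equal(es0$pooled$mean, 0)
  expect_equal(es0$pooled$sd, 0)

  es1 <- error_stats(ref, ref + 2)
  expect_equal(es1$pooled$mean, 2)
  expect_equal(es1$pooled$sd, 0)
  expect_equal(es1$per_filter$mean, c(2, 2))

  set.seed(12)
  ref2 <- matrix(rnorm(3600, sd = 40), 900, 4)
  es2 <- error_stats(ref2, ref2 + rnorm(3600, sd = 1.3))
  expect_lt(abs(es2$pooled$sd - 1.3) / 1.3, 0.1)

  expect_error(error_stats(ref, ref[1:10, ]), "differ")
})

test_that("conductance pairs round-trip exactly through CSV", {
  dm <- device_model()
  pair <- program_pair(map_to_conductance(unclass(build_filter_bank()), dm),
                       dm, seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_pair_csv(pair, f)
  back <- read_pair_csv(f, dm)
  expect_identical(unname(back$G_pos), unname(pair$G_pos))
  expect_identical(unname(back$G_neg), unname(pair$G_neg))
  expect_identical(back$scale_c, pair$scale_c)
  expect_identical(colnames(back$G_pos), colnames(pair$G_pos))
})
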