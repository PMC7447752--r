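# Synthetic LFP generation, plain-text I/O, segmentation, voltage scaling.

test_that("generation is deterministic under a fixed seed and has the default length", {
  a <- generate_clip("normal", n_samples = 4096, fs = 173.61, seed = 7)
  b <- generate_clip("normal", n_samples = 4096, fs = 173.61, seed = 7)
  expect_identical(a$samples, b$samples)
  expect_length(a$samples, 4096)
  expect_true(all(is.finite(a$samples)))
  c <- generate_clip("normal", seed = 8)
  expect_false(identical(a$samples, c$samples))
})

test_that("invalid labels and too-low sampling rates are rejected", {
  expect_error(generate_clip("preictal", seed = 1), "unknown label")
  expect_error(generate_clip("normal", fs = 50, seed = 1), "too low")
  expect_error(generate_clip("normal", n_samples = 100, seed = 1), ">= 600")
})

test_that("ictal low-band power exceeds normal by the configured ratio (Welch oracle)", {
  n_seeds <- 50
  p_ictal <- vapply(seq_len(n_seeds), function(s) {
    welch_band_power(generate_clip("ictal", seed = 1000 + s)$samples,
                     173.61, 0.5, 8)
  }, numeric(1))
  p_normal <- vapply(seq_len(n_seeds), function(s) {
    welch_band_power(generate_clip("normal", seed = 2000 + s)$samples,
                     173.61, 0.5, 8)
  }, numeric(1))
  expected <- sum(expected_band_power("ictal")[c("delta", "theta")]) /
    sum(expected_band_power("normal")[c("delta", "theta")])
  measured <- mean(p_ictal) / mean(p_normal)
  expect_lt(abs(measured - expected) / expected, 0.2)
  # class ordering of expected low-band power
  low <- function(lb) sum(expected_band_power(lb)[c("delta", "theta")])
  expect_true(low("ictal") > low("interictal"))
  expect_true(low("interictal") > low("normal"))
})

test_that("clip files read back exactly and errors name the offending line", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1", "-2", "3"), f)
  clip <- read_clip_file(f, fs = 173.61, label = "normal")
  expect_equal(clip$samples, c(1, -2, 3))

  gen <- generate_clip("ictal", seed = 11)
  f2 <- withr::local_tempfile(fileext = ".txt")
  write_clip_file(gen, f2)
  back <- read_clip_file(f2, fs = gen$fs, label = gen$label)
  expect_identical(back$samples, gen$samples)

  f3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1", "abc", "3"), f3)
  expect_error(read_clip_file(f3), "line 2")
  f4 <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(0), f4)
  expect_error(read_clip_file(f4), "empty")
})

test_that("segmentation yields six 600-sample segments and conserves samples", {
  clip <- generate_clip("normal", n_samples = 4096, seed = 3)
  segs <- segment_clip(clip)
  expect_length(segs, 6)
  expect_true(all(vapply(segs, function(s) length(s$samples), integer(1)) == 600))
  expect_identical(attr(segs, "discarded"), 496L)
  # segments are consecutive from the start; the trailing samples are dropped
  expect_identical(segs[[1]]$samples, clip$samples[1:600])
  expect_identical(segs[[6]]$samples, clip$samples[3001:3600])

  exact <- generate_clip("normal", n_samples = 3600, seed = 3)
  segs2 <- segment_clip(exact)
  expect_length(segs2, 6)
  expect_identical(attr(segs2, "discarded"), 0L)

  short <- generate_clip("normal", n_samples = 700, seed = 3)
  short$samples <- short$samples[1:599]
  expect_error(segment_clip(short), "at least 600")

  # conservation property across lengths
  for (n in c(650L, 1234L, 2999L, 4096L, 5000L)) {
    cl <- generate_clip("normal", n_samples = n, seed = 5)
    sg <- segment_clip(cl)
    expect_equal(600L * length(sg) + attr(sg, "discarded"), n)
    expect_lte(length(sg), 6L)
  }
})

test_that("voltage conversion is linear, auto-scales to the read ceiling, and guards overrange", {
  z <- generate_clip("normal", n_samples = 600, seed = 2)
  z$samples <- numeric(600)
  expect_equal(to_voltage(z, gain = 0.001)$volts, numeric(600))

  x <- c(-50, 100, 200)
  tr <- to_voltage(x, v_read_max = 0.2, gain = "auto", fs = 173.61)
  expect_equal(tr$gain, 0.001)
  expect_equal(max(abs(tr$volts)), 0.2)

  tr1 <- to_voltage(x, gain = 1e-4, fs = 173.61)
  tr2 <- to_voltage(2 * x, gain = 1e-4, fs = 173.61)
  expect_equal(tr2$volts, 2 * tr1$volts)

  expect_error(to_voltage(x, gain = 0.01, fs = 173.61), "v_read_max")
  clipped <- to_voltage(x, gain = 0.01, fs = 173.61, clip_overrange = TRUE)
  expect_equal(max(abs(clipped$volts)), 0.2)
})

test_that("300 clips yield exactly 1800 segments, 600 per class", {
  clips <- make_test_clips(clips_per_class = 4L, seed = 9, n_samples = 4096L)
  segs <- unlist(lapply(clips, segment_clip), recursive = FALSE)
  expect_length(segs, 4 * 3 * 6)
  labs <- vapply(segs, function(s) s$label, character(1))
  expect_true(all(table(labs) == 24))
})
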