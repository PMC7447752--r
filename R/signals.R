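# Synthetic epilepsy-like LFP clips: generation, plain-text I/O, segmentation
# and voltage conditioning.

CLASS_LABELS <- c("normal", "interictal", "ictal")

# Canonical neural oscillation band edges in Hz.
BAND_EDGES <- list(
  delta = c(0.5, 4),
  theta = c(4, 8),
  alpha = c(8, 12),
  beta  = c(12, 30)
)

#' Default per-class parameters for the synthetic LFP generator
#'
#' Each class carries an overall amplitude scale (standard deviation, in
#' microvolts, of a unit-weight band component), relative band weights over
#' the delta/theta/alpha/beta bands, and a per-clip lognormal gain jitter
#' (`amplitude_jitter`, the sd on the log scale) emulating the
#' clip-to-clip amplitude variability of real recordings. The ictal class
#' additionally mixes a continuous rhythmic ~3 Hz spike-and-wave discharge
#' (zero-mean over a cycle, as an AC-coupled recording chain enforces)
#' whose peak amplitude is several-fold the normal-class background,
#' emulating the large low-frequency rhythmic activity of a seizure.
#'
#' The induced ordering of expected low-band (delta + theta) power is
#' ictal > interictal > normal.
#'
#' @return Named list with one entry per class (`normal`, `interictal`,
#'   `ictal`); each entry has `amplitude` (uV), `band_weights` (length-4
#'   named vector), `amplitude_jitter` (lognormal sd), and for ictal a
#'   `spike` list (`amplitude` uV peak, `freq` Hz, `spike_frac`,
#'   `spike_width` as fractions of the cycle).
#' @export
default_class_params <- function() {
  list(
    normal = list(
      amplitude = 40,
      band_weights = c(delta = 1.0, theta = 0.8, alpha = 0.6, beta = 0.5),
      amplitude_jitter = 0.2
    ),
    interictal = list(
      amplitude = 70,
      band_weights = c(delta = 1.3, theta = 1.0, alpha = 0.7, beta = 0.5),
      amplitude_jitter = 0.2
    ),
    ictal = list(
      amplitude = 120,
      band_weights = c(delta = 1.6, theta = 1.2, alpha = 0.8, beta = 0.6),
      amplitude_jitter = 0.2,
      spike = list(amplitude = 400, freq = 3, spike_frac = 0.15,
                   spike_width = 0.04)
    )
  )
}

new_clip <- function(samples, fs, label, clip_id) {
  structure(
    list(samples = as.numeric(samples), fs = fs, label = label,
         clip_id = clip_id),
    class = "memfir_clip"
  )
}

#' @export
print.memfir_clip <- function(x, ...) {
  cat(sprintf("<memfir_clip> %s: %d samples @ %.4g Hz, label '%s'\n",
              x$clip_id, length(x$samples), x$fs, x$label))
  cat(sprintf("  range [%.3g, %.3g] uV, sd %.3g uV\n",
              min(x$samples), max(x$samples), sd(x$samples)))
  invisible(x)
}

# One period of the spike-and-wave discharge template, zero-mean (the
# recording chain is AC-coupled, so a periodic discharge carries no DC) and
# peak-normalized to 1. A narrow Gaussian spike is followed by a rounded
# slow half-sine wave.
spike_wave_template <- function(period_samples, spike_frac = 0.15,
                                spike_width = 0.04) {
  t <- (seq_len(period_samples) - 1) / period_samples
  spike <- exp(-0.5 * ((t - spike_frac) / spike_width)^2)
  wave_start <- spike_frac + 3 * spike_width
  wave <- ifelse(
    t > wave_start,
    0.45 * sin(pi * (t - wave_start) / (1 - wave_start)),
    0
  )
  tpl <- spike + wave
  tpl <- tpl - mean(tpl)
  tpl / max(abs(tpl))
}

# Band-limited unit-variance Gaussian noise via a zero-phase Butterworth
# band-pass applied to white noise (padded to suppress filter transients).
band_noise <- function(n, fs, f_low, f_high) {
  pad <- min(n, 2000L)
  w <- c(f_low, f_high) / (fs / 2)
  bf <- signal::butter(2, w, type = "pass")
  x <- rnorm(n + 2L * pad)
  y <- signal::filtfilt(bf, x)
  y <- y[(pad + 1L):(pad + n)]
  y / sd(y)
}

#' Generate a synthetic epilepsy-like LFP clip
#'
#' Draws one single-channel clip as a sum of band-limited Gaussian noise
#' components (one per delta/theta/alpha/beta band, each unit-variance and
#' scaled by `amplitude * band_weight`) plus, for the ictal class, a
#' continuous 3 Hz spike-and-wave discharge with random phase. Amplitudes
#' are in microvolts.
#'
#' @param label One of `"normal"`, `"interictal"`, `"ictal"`.
#' @param n_samples Clip length; default 4096 samples.
#' @param fs Sampling frequency in Hz; must be at least twice the highest
#'   band edge (>= 60 Hz). Default 173.61 Hz.
#' @param seed Integer seed for reproducibility (optional).
#' @param class_params Per-class generator parameters; see
#'   [default_class_params()].
#' @param clip_id Identifier stored in the clip.
#' @return A `memfir_clip` object (samples in uV, `fs`, `label`, `clip_id`).
#' @examples
#' clip <- generate_clip("ictal", seed = 7)
#' clip
#' @export
generate_clip <- function(label, n_samples = 4096, fs = 173.61, seed = NULL,
                          class_params = default_class_params(),
                          clip_id = paste0(label, "_", seed %||% "x")) {
  label <- as.character(label)
  if (!label %in% names(class_params)) {
    stop_memfir("unknown label '", label, "'; expected one of ",
                paste(names(class_params), collapse = ", "))
  }
  if (n_samples < 600) stop_memfir("n_samples must be >= 600")
  max_edge <- max(vapply(BAND_EDGES, max, numeric(1)))
  if (fs < 2 * max_edge) {
    stop_memfir("fs = ", fs, " Hz is too low; need fs >= ", 2 * max_edge,
                " Hz for the ", max_edge, " Hz band edge")
  }
  p <- class_params[[label]]
  with_seed(seed, {
    gain_jit <- exp(rnorm(1L, 0, p$amplitude_jitter %||% 0))
    x <- numeric(n_samples)
    for (band in names(BAND_EDGES)) {
      e <- BAND_EDGES[[band]]
      w <- p$band_weights[[band]]
      if (w > 0) x <- x + p$amplitude * w * band_noise(n_samples, fs, e[1], e[2])
    }
    if (!is.null(p$spike)) {
      sp <- p$spike
      period <- max(8L, round(fs / sp$freq))
      tpl <- spike_wave_template(period, sp$spike_frac, sp$spike_width)
      phase <- sample.int(period, 1L)
      idx <- ((seq_len(n_samples) + phase - 1L) %% period) + 1L
      x <- x + sp$amplitude * tpl[idx]
    }
    new_clip(gain_jit * x, fs, label, clip_id)
  })
}

#' Expected per-band signal power of the synthetic generator
#'
#' Analytic prediction of the per-band variance (uV^2) of a generated clip:
#' each band-noise component contributes `(amplitude * weight)^2` to its
#' band, and the ictal spike-and-wave discharge contributes its harmonic
#' powers (computed from the discrete Fourier series of one template period)
#' to whichever band each harmonic falls in. The per-clip lognormal gain
#' jitter scales the expectation by `exp(2 * amplitude_jitter^2)`. Used as
#' an independent check of the generator's spectral content.
#'
#' @inheritParams generate_clip
#' @return Named numeric vector of expected variance per band (uV^2).
#' @export
expected_band_power <- function(label, fs = 173.61,
                                class_params = default_class_params()) {
  p <- class_params[[label]]
  if (is.null(p)) stop_memfir("unknown label '", label, "'")
  pow <- vapply(names(BAND_EDGES), function(band) {
    (p$amplitude * p$band_weights[[band]])^2
  }, numeric(1))
  names(pow) <- names(BAND_EDGES)
  if (!is.null(p$spike)) {
    sp <- p$spike
    period <- max(8L, round(fs / sp$freq))
    tpl <- sp$amplitude * spike_wave_template(period, sp$spike_frac,
                                              sp$spike_width)
    co <- stats::fft(tpl) / period
    # harmonic j sits at j * fs / period Hz and carries power 2|c_j|^2
    for (j in seq_len(floor(period / 2))) {
      fj <- j * fs / period
      for (band in names(BAND_EDGES)) {
        e <- BAND_EDGES[[band]]
        if (fj > e[1] && fj <= e[2]) {
          pow[band] <- pow[band] + 2 * Mod(co[j + 1])^2
        }
      }
    }
  }
  pow * exp(2 * (p$amplitude_jitter %||% 0)^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a plain-text LFP clip (one sample value per line)
#'
#' Reads the widely used plain-text dialect of single-channel EEG/LFP clips:
#' one numeric sample (in uV) per line.
#'
#' @param path File path.
#' @param fs Sampling frequency in Hz to attach to the clip.
#' @param label Class label to attach (`"normal"`, `"interictal"`,
#'   `"ictal"`, or any string).
#' @param clip_id Identifier; defaults to the file name without extension.
#' @return A `memfir_clip`.
#' @export
read_clip_file <- function(path, fs = 173.61, label = "unknown",
                           clip_id = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop_memfir("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_memfir("empty clip file: ", path)
  vals <- suppressWarnings(as.numeric(lines))
  bad <- which(!is.finite(vals))
  if (length(bad) > 0L) {
    stop_memfir("non-numeric sample at line ", bad[1], " of ", path,
                ": '", lines[bad[1]], "'")
  }
  new_clip(vals, fs, label, clip_id)
}

#' Write a clip in the plain-text one-value-per-line dialect
#'
#' Values are written with 17 significant digits so a read/write round trip
#' reproduces the samples exactly.
#'
#' @param clip A `memfir_clip`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clip_file <- function(clip, path) {
  stopifnot(inherits(clip, "memfir_clip"))
  writeLines(format_full(clip$samples), path)
  invisible(path)
}

#' Split a clip into consecutive 600-sample segments
#'
#' Segments are consecutive and non-overlapping starting at the first
#' sample; at most six segments are taken and any trailing remainder is
#' discarded (a 4096-sample clip yields six segments and 496 discarded
#' samples).
#'
#' @param clip A `memfir_clip` of at least 600 samples.
#' @param segment_length Samples per segment (default 600).
#' @param max_segments Cap on the number of segments (default 6).
#' @return List of `memfir_segment` objects; attribute `discarded` holds the
#'   number of unused trailing samples.
#' @export
segment_clip <- function(clip, segment_length = 600L, max_segments = 6L) {
  stopifnot(inherits(clip, "memfir_clip"))
  n <- length(clip$samples)
  if (n < segment_length) {
    stop_memfir("clip '", clip$clip_id, "' has ", n,
                " samples; need at least ", segment_length)
  }
  k <- min(n %/% segment_length, max_segments)
  segs <- lapply(seq_len(k) - 1L, function(i) {
    structure(
      list(
        samples = clip$samples[(i * segment_length + 1L):((i + 1L) * segment_length)],
        fs = clip$fs,
        parent_clip_id = clip$clip_id,
        segment_index = i,
        label = clip$label
      ),
      class = "memfir_segment"
    )
  })
  attr(segs, "discarded") <- n - k * segment_length
  segs
}

#' @export
print.memfir_segment <- function(x, ...) {
  cat(sprintf("<memfir_segment> %s[%d]: %d samples, label '%s'\n",
              x$parent_clip_id, x$segment_index, length(x$samples), x$label))
  invisible(x)
}

#' Convert a segment (uV) to an analog read-voltage trace (V)
#'
#' Applies a linear gain (V per uV) so the trace can be streamed into the
#' crossbar as analog voltage pulses. `gain = "auto"` scales the largest
#' absolute sample of this input to `v_read_max`; in a multi-clip experiment
#' pass the dataset-wide gain explicitly so all traces share one scale.
#'
#' @param segment A `memfir_segment`, `memfir_clip`, or numeric vector (uV).
#' @param v_read_max Read-voltage ceiling in volts (default 0.2 V).
#' @param gain Numeric gain in V/uV, or `"auto"`.
#' @param clip_overrange If `TRUE`, clip out-of-range voltages to
#'   `v_read_max` instead of raising an error.
#' @param fs Sampling rate, required only for bare numeric input.
#' @return A `memfir_trace` with fields `volts`, `fs`, `gain`, `v_read_max`.
#' @export
to_voltage <- function(segment, v_read_max = 0.2, gain = "auto",
                       clip_overrange = FALSE, fs = NULL) {
  if (inherits(segment, c("memfir_segment", "memfir_clip"))) {
    samples <- segment$samples
    fs <- segment$fs
  } else {
    samples <- as.numeric(segment)
    if (is.null(fs)) stop_memfir("fs must be given for numeric input")
  }
  assert_finite(samples, "samples")
  if (identical(gain, "auto")) {
    m <- max(abs(samples))
    gain <- if (m > 0) v_read_max / m else 1
  }
  if (!is.numeric(gain) || gain <= 0) stop_memfir("gain must be positive")
  volts <- gain * samples
  over <- abs(volts) > v_read_max * (1 + 1e-12)
  if (any(over)) {
    if (!clip_overrange) {
      stop_memfir("voltage trace exceeds v_read_max = ", v_read_max,
                  " V (max ", signif(max(abs(volts)), 4),
                  " V); lower the gain or set clip_overrange = TRUE")
    }
    volts <- pmin(pmax(volts, -v_read_max), v_read_max)
  }
  structure(
    list(volts = volts, fs = fs, gain = gain, v_read_max = v_read_max),
    class = "memfir_trace"
  )
}

#' @export
print.memfir_trace <- function(x, ...) {
  cat(sprintf("<memfir_trace> %d samples @ %.4g Hz, gain %.4g V/uV, peak %.4g V\n",
              length(x$volts), x$fs, x$gain, max(abs(x$volts))))
  invisible(x)
}
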