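# Linear-phase FIR band-pass design, the filter-bank coefficient matrix, and
# the software reference (oracle) filter.

#' Specify a linear-phase FIR band-pass filter
#'
#' @param band_name Band label, conventionally one of `"delta"`, `"theta"`,
#'   `"alpha"`, `"beta"`.
#' @param f_low,f_high Band edges in Hz (`0 < f_low < f_high < fs/2`). The
#'   edges follow the window-method convention (-6 dB points).
#' @param order Filter order K (even, type-I linear phase); K + 1 taps.
#'   Default 120.
#' @param fs Sampling frequency in Hz. Default 173.61 Hz.
#' @param window Window name; only `"hamming"` is provided.
#' @return A `memfir_filter_spec`.
#' @export
filter_spec <- function(band_name, f_low, f_high, order = 120L, fs = 173.61,
                        window = "hamming") {
  order <- as.integer(order)
  if (order %% 2L != 0L) stop_memfir("filter order must be even (type-I linear phase)")
  if (!(f_low > 0 && f_low < f_high)) stop_memfir("need 0 < f_low < f_high")
  if (f_high >= fs / 2) {
    stop_memfir("f_high = ", f_high, " Hz is at or above Nyquist (", fs / 2, " Hz)")
  }
  structure(
    list(band_name = band_name, f_low = f_low, f_high = f_high,
         order = order, fs = fs, window = window),
    class = "memfir_filter_spec"
  )
}

#' Default delta/theta/alpha/beta filter specifications
#'
#' The four canonical neural oscillation bands: delta 0.5-4 Hz, theta
#' 4-8 Hz, alpha 8-12 Hz, beta 12-30 Hz.
#'
#' @inheritParams filter_spec
#' @return List of four `memfir_filter_spec` objects.
#' @export
default_band_specs <- function(order = 120L, fs = 173.61) {
  lapply(names(BAND_EDGES), function(b) {
    e <- BAND_EDGES[[b]]
    filter_spec(b, e[1], e[2], order = order, fs = fs)
  })
}

#' Design one band-pass filter column
#'
#' Windowed-sinc (Hamming) linear-phase band-pass design, followed by an
#' exact DC-nulling correction: the coefficient mean is subtracted so the
#' zero-frequency gain is identically zero. The correction preserves the
#' even symmetry `h(k) = h(K - k)` and matters only for bands whose lower
#' edge is narrower than the window's transition width (the 0.5 Hz delta
#' edge at K = 120); elsewhere it is numerically negligible.
#'
#' @param spec A `memfir_filter_spec`.
#' @param dc_null Apply the DC-nulling correction (default `TRUE`).
#' @return Numeric vector of K + 1 coefficients.
#' @export
design_bandpass <- function(spec, dc_null = TRUE) {
  stopifnot(inherits(spec, "memfir_filter_spec"))
  if (spec$window != "hamming") stop_memfir("only the Hamming window is supported")
  h <- signal::fir1(spec$order, c(spec$f_low, spec$f_high) / (spec$fs / 2),
                    type = "pass")
  h <- as.numeric(h)
  h <- (h + rev(h)) / 2  # enforce exact type-I symmetry against fp residue
  if (dc_null) h <- h - mean(h)
  h
}

#' Magnitude frequency response of an FIR filter
#'
#' Direct evaluation of |H(f)| = |sum_k h(k) exp(-i 2 pi f k / fs)| at the
#' requested frequencies; independent of any filtering code path, so it
#' serves as the response oracle in tests.
#'
#' @param h Coefficient vector.
#' @param f Frequencies in Hz.
#' @param fs Sampling frequency in Hz.
#' @return Numeric vector of magnitude gains.
#' @export
fir_response <- function(h, f, fs) {
  k <- seq_along(h) - 1
  vapply(f, function(ff) Mod(sum(h * exp(-2i * pi * ff * k / fs))), numeric(1))
}

#' Assemble the filter-bank coefficient matrix
#'
#' Column m holds the K + 1 coefficients of filter m, so filtering is the
#' matrix product of the lagged-input row vector with this matrix. Under
#' differential conductance-pair mapping each coefficient costs two
#' memristor devices, hence the bank needs `2 * (K + 1) * M` devices
#' (968 for four 120-order filters).
#'
#' @param specs List of `memfir_filter_spec` sharing `fs` and `order`.
#' @param dc_null Passed to [design_bandpass()].
#' @return A `memfir_bank`: numeric matrix of dim (K+1) x M with band-named
#'   columns and attributes `specs`, `fs`, `order`.
#' @export
build_filter_bank <- function(specs = default_band_specs(), dc_null = TRUE) {
  if (length(specs) == 0L) stop_memfir("need at least one filter spec")
  if (inherits(specs, "memfir_filter_spec")) specs <- list(specs)
  fs <- unique(vapply(specs, function(s) s$fs, numeric(1)))
  ord <- unique(vapply(specs, function(s) s$order, integer(1)))
  if (length(fs) != 1L || length(ord) != 1L) {
    stop_memfir("all filters in a bank must share fs and order")
  }
  H <- vapply(specs, design_bandpass, numeric(ord + 1L), dc_null = dc_null)
  colnames(H) <- vapply(specs, function(s) s$band_name, character(1))
  structure(H, specs = specs, fs = fs, order = ord,
            class = c("memfir_bank", "matrix", "array"))
}

#' @export
print.memfir_bank <- function(x, ...) {
  cat(sprintf("<memfir_bank> %d taps x %d filters @ %.4g Hz (order %d)\n",
              nrow(x), ncol(x), attr(x, "fs"), attr(x, "order")))
  for (s in attr(x, "specs")) {
    cat(sprintf("  %-6s %.3g-%.3g Hz\n", s$band_name, s$f_low, s$f_high))
  }
  cat(sprintf("  differential-pair device demand: %d\n", device_count(x)))
  invisible(x)
}

#' Number of memristor devices needed under differential mapping
#'
#' Every signed value (filter coefficient or synaptic weight) is carried by
#' a pair of non-negative conductances, so the device demand of a matrix is
#' twice its element count: 242 per 121-tap filter, 968 for the four-filter
#' bank, 126 for the 21 x 3 perceptron.
#'
#' @param x A `memfir_bank`, `memfir_pair`, `memfir_perceptron`, or matrix.
#' @return Integer device count.
#' @export
device_count <- function(x) {
  if (inherits(x, "memfir_pair")) return(2L * length(x$G_pos))
  if (inherits(x, "memfir_perceptron")) return(2L * length(x$W))
  2L * length(unclass(x))
}

#' Software reference FIR filter (the oracle)
#'
#' Direct-form causal convolution `y(n) = sum_{k=0}^{K} x(n-k) h(k)` with
#' zero padding before the start of the signal, so `y` has the same length
#' as `x`. All crossbar filtering results are validated against this
#' reference.
#'
#' @param x Input signal (numeric).
#' @param h Coefficients.
#' @return Filtered signal, same length as `x`.
#' @export
apply_fir_reference <- function(x, h) {
  if (length(h) == 0L) stop_memfir("empty coefficient vector")
  x <- as.numeric(x)
  if (length(x) == 0L) stop_memfir("empty input signal")
  y <- convolve(x, rev(h), type = "open")
  y[seq_along(x)]
}

#' Apply every filter of a bank via the software reference
#'
#' @param x Input signal (numeric) or `memfir_trace`.
#' @param bank A `memfir_bank`.
#' @return Matrix, one column per band, same rows as `length(x)`.
#' @export
apply_bank_reference <- function(x, bank) {
  if (inherits(x, "memfir_trace")) x <- x$volts
  H <- unclass(bank)
  y <- vapply(seq_len(ncol(H)), function(m) apply_fir_reference(x, H[, m]),
              numeric(length(x)))
  colnames(y) <- colnames(H)
  y
}

# Transition-band width at the upper band edge: distance between the
# frequencies (above the midband peak) where the response falls to 50% and
# to 10% of the midband gain. Measured on a fine grid with the response
# oracle.
transition_width <- function(h, spec, df = 0.01) {
  fmid <- (spec$f_low + spec$f_high) / 2
  gmid <- fir_response(h, fmid, spec$fs)
  f <- seq(fmid, spec$fs / 2, by = df)
  g <- fir_response(h, f, spec$fs) / gmid
  f50 <- f[which(g < 0.5)[1]]
  f10 <- f[which(g < 0.1)[1]]
  if (is.na(f50) || is.na(f10)) return(NA_real_)
  f10 - f50
}

#' Sweep the filter order and record transition widths and waveforms
#'
#' Re-designs the same band at several (even) orders, filters a test signal
#' with each design via the software reference, and reports the upper-edge
#' transition-band width per order. Higher orders sharpen the filter
#' (narrower transition band) at the cost of more taps/devices.
#'
#' @param orders Even integer orders, e.g. `seq(40, 200, 40)`.
#' @param test_signal Numeric signal to filter at every order.
#' @param spec Base `memfir_filter_spec` (its order is overridden).
#' @return A `memfir_sweep`: data frame with columns `order`, `n_taps`,
#'   `transition_width_hz`; attribute `waveforms` holds one filtered signal
#'   per order.
#' @export
order_sweep <- function(orders, test_signal, spec) {
  orders <- as.integer(orders)
  if (any(orders %% 2L != 0L)) stop_memfir("all orders must be even")
  rows <- lapply(orders, function(K) {
    sp <- filter_spec(spec$band_name, spec$f_low, spec$f_high, order = K,
                      fs = spec$fs, window = spec$window)
    h <- design_bandpass(sp)
    list(width = transition_width(h, sp),
         wave = apply_fir_reference(test_signal, h))
  })
  out <- data.frame(
    order = orders,
    n_taps = orders + 1L,
    transition_width_hz = vapply(rows, `[[`, numeric(1), "width")
  )
  attr(out, "waveforms") <- lapply(rows, `[[`, "wave")
  class(out) <- c("memfir_sweep", "data.frame")
  out
}

#' Plot the magnitude frequency responses of a filter bank
#'
#' @param x A `memfir_bank`.
#' @param f Frequencies in Hz (default: a fine grid up to Nyquist).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.memfir_bank <- function(x, f = NULL, ...) {
  fs <- attr(x, "fs")
  if (is.null(f)) f <- seq(0, fs / 2, length.out = 400)
  H <- unclass(x)
  G <- vapply(seq_len(ncol(H)), function(m) fir_response(H[, m], f, fs),
              numeric(length(f)))
  matplot(f, G, type = "l", lty = 1, xlab = "frequency (Hz)",
          ylab = "|H(f)|", ...)
  legend("topright", colnames(H), col = seq_len(ncol(H)), lty = 1, bty = "n")
  abline(h = 10^(-6 / 20), lty = 3)
  invisible(x)
}

#' Write / read a filter bank as CSV
#'
#' One column per band; a `#`-prefixed header line records `fs`, the order
#' and the band edges so the bank (with its specs) round-trips exactly.
#'
#' @param bank A `memfir_bank`.
#' @param path CSV path.
#' @return `path` invisibly (write); a `memfir_bank` (read).
#' @export
write_bank_csv <- function(bank, path) {
  specs <- attr(bank, "specs")
  meta <- paste0("# fs=", format_full(attr(bank, "fs")),
                 " order=", attr(bank, "order"),
                 " bands=", paste(vapply(specs, function(s) {
                   paste(s$band_name, format_full(s$f_low),
                         format_full(s$f_high), sep = ":")
                 }, character(1)), collapse = ","))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  writeLines(paste(colnames(bank), collapse = ","), con)
  m <- unclass(bank)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(format_full(m[i, ]), collapse = ","), con)
  }
  invisible(path)
}

#' @rdname write_bank_csv
#' @export
read_bank_csv <- function(path) {
  lines <- readLines(path)
  meta <- lines[1]
  if (!startsWith(meta, "# fs=")) stop_memfir("not a memfir bank CSV: ", path)
  fs <- as.numeric(sub("^# fs=([^ ]+).*", "\\1", meta))
  ord <- as.integer(sub(".* order=([0-9]+).*", "\\1", meta))
  bands_str <- sub(".* bands=", "", meta)
  specs <- lapply(strsplit(bands_str, ",")[[1]], function(s) {
    parts <- strsplit(s, ":")[[1]]
    filter_spec(parts[1], as.numeric(parts[2]), as.numeric(parts[3]),
                order = ord, fs = fs)
  })
  body <- read.csv(text = lines[-1], header = TRUE, check.names = FALSE)
  H <- as.matrix(body)
  structure(H, specs = specs, fs = fs, order = ord,
            class = c("memfir_bank", "matrix", "array"))
}
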