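# 1T1R crossbar simulation: differential conductance mapping, programming
# and read non-idealities, and analog matrix-vector readout (I = V * G).

#' Memristor device model
#'
#' Linear-conductance device with a bounded programmable range and two noise
#' sources: a one-off Gaussian programming error (absolute, uS, clipped back
#' into range) and a per-read multiplicative Gaussian read noise.
#'
#' @param g_min,g_max Conductance range in uS (default 2-20 uS).
#' @param program_sigma Programming-error standard deviation in uS
#'   (default 0.08 uS).
#' @param read_sigma_rel Relative read-noise standard deviation per
#'   device-read (default 0.008). Both noise defaults are calibrated
#'   jointly, with comparable contributions, so the pooled filter-bank
#'   output error is about 1.3-1.7% (sd) of the normal-class signal's
#'   peak-to-valley amplitude.
#' @param v_read_max Read-voltage ceiling in V (default 0.2 V).
#' @param t_read Read-pulse duration in seconds (default 50 ns), used by the
#'   power model.
#' @return A `memfir_device_model`.
#' @export
device_model <- function(g_min = 2, g_max = 20, program_sigma = 0.08,
                         read_sigma_rel = 0.008, v_read_max = 0.2,
                         t_read = 50e-9) {
  if (!(g_min > 0 && g_min < g_max)) stop_memfir("need 0 < g_min < g_max")
  if (program_sigma < 0 || read_sigma_rel < 0) stop_memfir("noise sigmas must be >= 0")
  structure(
    list(g_min = g_min, g_max = g_max, program_sigma = program_sigma,
         read_sigma_rel = read_sigma_rel, v_read_max = v_read_max,
         t_read = t_read),
    class = "memfir_device_model"
  )
}

#' @export
print.memfir_device_model <- function(x, ...) {
  cat(sprintf(paste0(
    "<memfir_device_model> G in [%.3g, %.3g] uS, program sigma %.3g uS,\n",
    "  read sigma %.3g (relative), v_read_max %.3g V, t_read %.3g s\n"),
    x$g_min, x$g_max, x$program_sigma, x$read_sigma_rel, x$v_read_max,
    x$t_read))
  invisible(x)
}

#' Map a signed matrix onto differential conductance pairs
#'
#' Each signed entry w is carried by two devices: `G+ = g_base + c * max(w, 0)`
#' and `G- = g_base + c * max(-w, 0)` with `g_base = g_min` and scale
#' `c = (g_max - g_min) / max|w|`, so the largest-magnitude entry uses the
#' full conductance range and `(G+ - G-) / c` reconstructs the matrix
#' exactly when no noise is applied.
#'
#' @param target Numeric matrix (or vector) of signed values.
#' @param dm A [device_model()].
#' @return A `memfir_pair` with fields `G_pos`, `G_neg` (uS), `scale_c`
#'   (uS per target unit), `g_base`, `device_model`.
#' @export
map_to_conductance <- function(target, dm = device_model()) {
  if (is.null(dim(target))) target <- matrix(as.numeric(target), ncol = 1)
  target <- array(as.numeric(target), dim = dim(target),
                  dimnames = dimnames(target))
  assert_finite(target, "target entries")
  m <- max(abs(target))
  scale_c <- if (m > 0) (dm$g_max - dm$g_min) / m else 1
  G_pos <- dm$g_min + scale_c * pmax(target, 0)
  G_neg <- dm$g_min + scale_c * pmax(-target, 0)
  structure(
    list(G_pos = G_pos, G_neg = G_neg, scale_c = scale_c, g_base = dm$g_min,
         device_model = dm),
    class = "memfir_pair"
  )
}

#' @export
print.memfir_pair <- function(x, ...) {
  cat(sprintf(paste0(
    "<memfir_pair> %d x %d coefficients -> %d devices, G in [%.3g, %.3g] uS,\n",
    "  scale %.4g uS/unit, base %.3g uS%s\n"),
    nrow(x$G_pos), ncol(x$G_pos), device_count(x),
    min(x$G_pos, x$G_neg), max(x$G_pos, x$G_neg), x$scale_c, x$g_base,
    if (isTRUE(attr(x, "programmed"))) " (programmed)" else ""))
  invisible(x)
}

#' Reconstruct the signed target matrix from a conductance pair
#'
#' @param pair A `memfir_pair`.
#' @return `(G_pos - G_neg) / scale_c`.
#' @export
reconstruct_target <- function(pair) {
  (pair$G_pos - pair$G_neg) / pair$scale_c
}

#' Program a conductance pair with device-level write error
#'
#' Adds independent Gaussian perturbations (sd `program_sigma` uS) to every
#' device and clips the result back into `[g_min, g_max]`, emulating
#' write-verify residual error.
#'
#' @param pair A `memfir_pair`.
#' @param dm Device model (defaults to the pair's).
#' @param seed Optional integer seed.
#' @return The programmed `memfir_pair` (attribute `programmed = TRUE`).
#' @export
program_pair <- function(pair, dm = pair$device_model, seed = NULL) {
  stopifnot(inherits(pair, "memfir_pair"))
  if (dm$program_sigma > 0) {
    with_seed(seed, {
      pair$G_pos <- pair$G_pos + rnorm(length(pair$G_pos), 0, dm$program_sigma)
      pair$G_neg <- pair$G_neg + rnorm(length(pair$G_neg), 0, dm$program_sigma)
    })
    pair$G_pos <- pmin(pmax(pair$G_pos, dm$g_min), dm$g_max)
    pair$G_neg <- pmin(pmax(pair$G_neg, dm$g_min), dm$g_max)
  }
  attr(pair, "programmed") <- TRUE
  pair
}

#' One analog matrix-vector read: column currents under an input voltage
#'
#' Computes `I_m = sum_k V_k (G+[k,m] - G-[k,m])` in uA (V x uS). With read
#' noise enabled, every device conductance is perturbed multiplicatively by
#' `N(0, read_sigma_rel)` for this read.
#'
#' @param V Input voltage vector (V), length = rows of the pair; entries
#'   must not exceed `v_read_max` in magnitude.
#' @param pair A `memfir_pair`.
#' @param dm Device model (defaults to the pair's).
#' @param seed Optional seed.
#' @param read_noise Apply read noise (default `TRUE`; ignored when
#'   `read_sigma_rel` is 0).
#' @return Numeric current vector (uA), one entry per column.
#' @export
read_mvm <- function(V, pair, dm = pair$device_model, seed = NULL,
                     read_noise = TRUE) {
  V <- as.numeric(V)
  if (length(V) != nrow(pair$G_pos)) {
    stop_memfir("input length ", length(V), " does not match the array's ",
                nrow(pair$G_pos), " rows")
  }
  if (max(abs(V)) > dm$v_read_max * (1 + 1e-12)) {
    stop_memfir("input voltage exceeds v_read_max = ", dm$v_read_max, " V")
  }
  Gp <- pair$G_pos
  Gn <- pair$G_neg
  if (read_noise && dm$read_sigma_rel > 0) {
    with_seed(seed, {
      Gp <- Gp * (1 + rnorm(length(Gp), 0, dm$read_sigma_rel))
      Gn <- Gn * (1 + rnorm(length(Gn), 0, dm$read_sigma_rel))
    })
  }
  as.numeric(crossprod(Gp - Gn, V))
}

# Lagged-input matrix for streaming: row n holds [V(n), V(n-1), ..., V(n-K)]
# with zeros before the start of the trace.
lag_matrix <- function(v, n_taps) {
  stats::embed(c(numeric(n_taps - 1L), v), n_taps)
}

#' Stream a voltage trace through the crossbar filter bank
#'
#' At every time step the lagged input window (zero-padded before the start)
#' is applied to the array and the column currents are recorded, then scaled
#' by the trans-impedance gain into output volts. With noise disabled the
#' result equals the software reference filter applied to the same trace.
#'
#' Read noise is sampled in aggregated form: the noise contribution of a
#' column at one time step is a sum of independent per-device terms and is
#' therefore exactly Gaussian with variance
#' `read_sigma_rel^2 * sum_k (V_k G[k,m])^2` (positive and negative devices
#' combined), so one draw per column-timestep reproduces the per-device law
#' exactly.
#'
#' @param trace A `memfir_trace` (or numeric voltage vector).
#' @param pair A `memfir_pair` holding the filter-bank coefficients
#'   (typically programmed via [program_pair()]).
#' @param dm Device model (defaults to the pair's).
#' @param tia_gain Trans-impedance gain in V/uA, or `"auto"` for
#'   `1 / scale_c`, which makes the output directly comparable to the
#'   reference filter applied to the trace.
#' @param seed Optional seed for the read noise.
#' @param read_noise Apply read noise (default `TRUE`).
#' @return Matrix (trace length x filters) of output volts, band-named
#'   columns; attribute `tia_gain` records the gain used.
#' @export
filter_signal_crossbar <- function(trace, pair, dm = pair$device_model,
                                   tia_gain = "auto", seed = NULL,
                                   read_noise = TRUE) {
  v <- if (inherits(trace, "memfir_trace")) trace$volts else as.numeric(trace)
  if (max(abs(v)) > dm$v_read_max * (1 + 1e-12)) {
    stop_memfir("trace exceeds v_read_max = ", dm$v_read_max, " V")
  }
  n_taps <- nrow(pair$G_pos)
  X <- lag_matrix(v, n_taps)
  I <- X %*% (pair$G_pos - pair$G_neg)
  if (read_noise && dm$read_sigma_rel > 0) {
    sd_I <- dm$read_sigma_rel * sqrt(X^2 %*% (pair$G_pos^2 + pair$G_neg^2))
    I <- I + with_seed(seed, rnorm(length(I))) * sd_I
  }
  if (identical(tia_gain, "auto")) tia_gain <- 1 / pair$scale_c
  out <- I * tia_gain
  colnames(out) <- colnames(pair$G_pos)
  attr(out, "tia_gain") <- tia_gain
  out
}

#' Error statistics between reference and measured waveforms
#'
#' Errors are `measured - reference`. Reports the mean and standard
#' deviation per filter and pooled over all filters, plus both expressed as
#' a percentage of the reference's pooled peak-to-valley amplitude.
#'
#' @param reference,measured Equal-dimension matrices (or vectors) of
#'   waveform values.
#' @return A `memfir_error_stats`: list with `per_filter` (data frame:
#'   filter, mean, sd), `pooled` (mean, sd), `peak_to_valley`,
#'   `pooled_mean_pct`, `pooled_sd_pct`.
#' @export
error_stats <- function(reference, measured) {
  reference <- as.matrix(reference)
  measured <- as.matrix(measured)
  if (!all(dim(reference) == dim(measured))) {
    stop_memfir("reference and measured dimensions differ")
  }
  err <- measured - reference
  nm <- colnames(reference) %||% paste0("f", seq_len(ncol(reference)))
  per <- data.frame(
    filter = nm,
    mean = colMeans(err),
    sd = apply(err, 2, sd),
    row.names = NULL
  )
  ptv <- max(reference) - min(reference)
  pooled_mean <- mean(err)
  pooled_sd <- sd(as.numeric(err))
  structure(
    list(per_filter = per,
         pooled = list(mean = pooled_mean, sd = pooled_sd),
         peak_to_valley = ptv,
         pooled_mean_pct = 100 * abs(pooled_mean) / ptv,
         pooled_sd_pct = 100 * pooled_sd / ptv),
    class = "memfir_error_stats"
  )
}

#' @export
print.memfir_error_stats <- function(x, ...) {
  cat("<memfir_error_stats>\n")
  for (i in seq_len(nrow(x$per_filter))) {
    cat(sprintf("  %-6s mu = %+.4g, sigma = %.4g\n",
                x$per_filter$filter[i], x$per_filter$mean[i],
                x$per_filter$sd[i]))
  }
  cat(sprintf("  pooled mu = %+.4g (%.2f%% of peak-to-valley), sigma = %.4g (%.2f%%)\n",
              x$pooled$mean, x$pooled_mean_pct, x$pooled$sd, x$pooled_sd_pct))
  invisible(x)
}

#' Write / read a conductance pair as CSV
#'
#' Long format (`row,col,g_pos,g_neg`) with a `#` header line carrying
#' `scale_c`, `g_base` and column names; values round-trip exactly.
#'
#' @param pair A `memfir_pair`.
#' @param path CSV path.
#' @param dm Device model to attach on read.
#' @return `path` invisibly (write); a `memfir_pair` (read).
#' @export
write_pair_csv <- function(pair, path) {
  nm <- colnames(pair$G_pos) %||% paste0("c", seq_len(ncol(pair$G_pos)))
  meta <- paste0("# scale_c=", format_full(pair$scale_c),
                 " g_base=", format_full(pair$g_base),
                 " cols=", paste(nm, collapse = ";"))
  idx <- expand.grid(row = seq_len(nrow(pair$G_pos)),
                     col = seq_len(ncol(pair$G_pos)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  writeLines("row,col,g_pos,g_neg", con)
  writeLines(paste(idx$row, idx$col,
                   format_full(pair$G_pos[as.matrix(idx)]),
                   format_full(pair$G_neg[as.matrix(idx)]), sep = ","), con)
  invisible(path)
}

#' @rdname write_pair_csv
#' @export
read_pair_csv <- function(path, dm = device_model()) {
  lines <- readLines(path)
  meta <- lines[1]
  if (!startsWith(meta, "# scale_c=")) stop_memfir("not a memfir pair CSV: ", path)
  scale_c <- as.numeric(sub("^# scale_c=([^ ]+).*", "\\1", meta))
  g_base <- as.numeric(sub(".* g_base=([^ ]+).*", "\\1", meta))
  nm <- strsplit(sub(".* cols=", "", meta), ";")[[1]]
  body <- read.csv(text = lines[-1], header = TRUE)
  nr <- max(body$row); nc <- max(body$col)
  G_pos <- matrix(NA_real_, nr, nc, dimnames = list(NULL, nm))
  G_neg <- G_pos
  G_pos[cbind(body$row, body$col)] <- body$g_pos
  G_neg[cbind(body$row, body$col)] <- body$g_neg
  structure(
    list(G_pos = G_pos, G_neg = G_neg, scale_c = scale_c, g_base = g_base,
         device_model = dm),
    class = "memfir_pair"
  )
}
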