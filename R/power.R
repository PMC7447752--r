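# Itemized power-efficiency accounting: memristor crossbar system versus a
# CMOS baseline, for a standard one-channel 0.1 s clip sampled at 10 kS/s.

#' Power-model assumptions
#'
#' All constants entering the power accounting, in SI units. The standard
#' workload is a one-channel 0.1 s clip sampled at 10 kS/s (1000 samples),
#' i.e. ten classification decisions per second. The per-device read power
#' uses the worst-case (maximum) conductance of 20 uS at the 0.2 V read
#' voltage. The CMOS references are a 64-filter 16-tap FIR front end
#' (0.53 mW at 7.1 kS/s) and a classifier consuming 273 uJ per 2 s epoch on
#' a 432-dimensional input at two classes, both linearly rescaled to this
#' system's dimensions (four 121-tap filters; 21 inputs, 3 classes, 10 Hz
#' decision rate).
#'
#' @param v_read Read voltage, V.
#' @param g_read Worst-case device conductance, S (20e-6).
#' @param t_read Read-pulse duration, s.
#' @param p_tia_filter TIA power per filter column, W.
#' @param p_tia_neuron TIA power per output neuron, W.
#' @param n_taps,n_filters Filter-bank dimensions.
#' @param n_inputs,n_classes Perceptron dimensions.
#' @param fs_standard Standard sampling rate, S/s.
#' @param clip_duration Standard clip length, s.
#' @param cmos_filter,cmos_decoder Reference-design parameter lists.
#' @return A `memfir_power_assumptions` list.
#' @export
power_assumptions <- function(v_read = 0.2,
                              g_read = 20e-6,
                              t_read = 50e-9,
                              p_tia_filter = 0.50e-3,
                              p_tia_neuron = 0.10e-3,
                              n_taps = 121L,
                              n_filters = 4L,
                              n_inputs = 21L,
                              n_classes = 3L,
                              fs_standard = 10e3,
                              clip_duration = 0.1,
                              cmos_filter = list(power = 0.53e-3,
                                                 n_filters = 64L,
                                                 n_taps = 16L,
                                                 fs = 7.1e3),
                              cmos_decoder = list(energy = 273e-6,
                                                  epoch = 2,
                                                  n_inputs = 18L * 3L * 8L,
                                                  n_classes = 2L,
                                                  rate = 0.5)) {
  a <- list(v_read = v_read, g_read = g_read, t_read = t_read,
            p_tia_filter = p_tia_filter, p_tia_neuron = p_tia_neuron,
            n_taps = n_taps, n_filters = n_filters, n_inputs = n_inputs,
            n_classes = n_classes, fs_standard = fs_standard,
            clip_duration = clip_duration, cmos_filter = cmos_filter,
            cmos_decoder = cmos_decoder)
  num <- unlist(a)
  if (any(!is.finite(num)) || any(num <= 0)) {
    stop_memfir("all power assumptions must be positive and finite")
  }
  structure(a, class = "memfir_power_assumptions")
}

#' Per-device read power
#'
#' Ohmic dissipation of one read: `P = v^2 * g`.
#'
#' @param v_read Read voltage, V.
#' @param g Device conductance, S.
#' @return Power in W (0.2 V at 20 uS gives 0.8 uW).
#' @export
memristor_read_power <- function(v_read, g) {
  if (v_read < 0 || g <= 0) stop_memfir("need v_read >= 0 and g > 0")
  v_read^2 * g
}

#' Filter-bank energy per sample point
#'
#' One sample point drives all taps of all filters for one read pulse:
#' `E = (P_read * n_taps * 2 + P_TIA) * t_read * n_filters`
#' (the factor 2 is the differential pair). Defaults give 138.7 pJ/sample.
#'
#' @param a A [power_assumptions()] object.
#' @return Energy in J per sample.
#' @export
filterbank_energy_per_sample <- function(a = power_assumptions()) {
  p_read <- memristor_read_power(a$v_read, a$g_read)
  (p_read * a$n_taps * 2 + a$p_tia_filter) * a$t_read * a$n_filters
}

#' Memristor-system power efficiencies
#'
#' Filter bank: energy per sample times the samples in a standard clip,
#' divided by the clip duration (1.39 uW/class with defaults). Perceptron:
#' one 21-input read per output neuron per decision
#' (`(P_read * 21 * 2 + P_TIA) * 3 * t_read / 0.1 s`; 0.20 nW/class).
#'
#' @param a A [power_assumptions()] object.
#' @return List with `filter`, `perceptron`, `total`, all in W/class.
#' @export
memristor_efficiencies <- function(a = power_assumptions()) {
  p_read <- memristor_read_power(a$v_read, a$g_read)
  samples_per_clip <- a$fs_standard * a$clip_duration
  filter <- filterbank_energy_per_sample(a) * samples_per_clip / a$clip_duration
  perceptron <- (p_read * a$n_inputs * 2 + a$p_tia_neuron) *
    a$n_classes * a$t_read / a$clip_duration
  list(filter = filter, perceptron = perceptron, total = filter + perceptron)
}

#' CMOS-baseline power efficiencies
#'
#' The reference FIR front end is scaled per tap and per sample rate to
#' four 121-tap filters at the standard rate; the reference classifier is
#' scaled per input dimension, per class and to the 10 Hz decision rate.
#' Defaults give 352.8 and 199.1 uW/class (the source arithmetic prints
#' 352.0 and 199.0 after intermediate rounding).
#'
#' @param a A [power_assumptions()] object.
#' @return List with `filter`, `decoder`, `total`, all in W/class.
#' @export
cmos_efficiencies <- function(a = power_assumptions()) {
  cf <- a$cmos_filter
  filter <- cf$power / (cf$n_filters * cf$n_taps) *
    (a$n_filters * a$n_taps) / cf$fs * a$fs_standard
  cd <- a$cmos_decoder
  decision_rate <- 1 / a$clip_duration
  decoder <- (cd$energy / cd$epoch) / cd$n_inputs * a$n_inputs /
    cd$n_classes * a$n_classes / cd$rate * decision_rate
  list(filter = filter, decoder = decoder, total = filter + decoder)
}

#' Itemized power report
#'
#' Computes every term of the power accounting at full precision and the
#' memristor-versus-CMOS efficiency ratio (~398x with defaults). Fields are
#' reported both in SI and in the conventional display units.
#'
#' @param a A [power_assumptions()] object.
#' @return A `memfir_power_report` list: `read_power_uW`,
#'   `filter_energy_pJ_per_sample`, `memristor` and `cmos` itemizations
#'   (W/class), display-unit scalars and `efficiency_ratio`.
#' @export
power_report <- function(a = power_assumptions()) {
  mem <- memristor_efficiencies(a)
  cmos <- cmos_efficiencies(a)
  structure(
    list(
      assumptions = a,
      read_power_uW = memristor_read_power(a$v_read, a$g_read) * 1e6,
      filter_energy_pJ_per_sample = filterbank_energy_per_sample(a) * 1e12,
      memristor = mem,
      cmos = cmos,
      memristor_filter_uW_per_class = mem$filter * 1e6,
      memristor_perceptron_nW_per_class = mem$perceptron * 1e9,
      memristor_total_uW_per_class = mem$total * 1e6,
      cmos_filter_uW_per_class = cmos$filter * 1e6,
      cmos_decoder_uW_per_class = cmos$decoder * 1e6,
      cmos_total_uW_per_class = cmos$total * 1e6,
      efficiency_ratio = cmos$total / mem$total
    ),
    class = "memfir_power_report"
  )
}

#' @export
print.memfir_power_report <- function(x, ...) {
  cat("<memfir_power_report>\n")
  cat(sprintf("  per-device read power     %8.3f uW\n", x$read_power_uW))
  cat(sprintf("  filter-bank energy        %8.2f pJ/sample\n",
              x$filter_energy_pJ_per_sample))
  cat("  memristor system:\n")
  cat(sprintf("    filter bank             %8.3f uW/class\n",
              x$memristor_filter_uW_per_class))
  cat(sprintf("    perceptron              %8.3f nW/class\n",
              x$memristor_perceptron_nW_per_class))
  cat(sprintf("    total                   %8.3f uW/class\n",
              x$memristor_total_uW_per_class))
  cat("  CMOS baseline:\n")
  cat(sprintf("    filter front end        %8.1f uW/class\n",
              x$cmos_filter_uW_per_class))
  cat(sprintf("    decoder                 %8.1f uW/class\n",
              x$cmos_decoder_uW_per_class))
  cat(sprintf("    total                   %8.1f uW/class\n",
              x$cmos_total_uW_per_class))
  cat(sprintf("  CMOS / memristor ratio    %8.1f x\n", x$efficiency_ratio))
  invisible(x)
}
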