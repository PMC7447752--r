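# End-to-end experiment orchestration: clips -> filter bank (reference and
# crossbar) -> biomarkers -> S.S./M.S./M.M. evaluation -> error analysis ->
# power report, with a reproducible manifest.

#' Experiment configuration
#'
#' Collects every tunable of the end-to-end run. Defaults mirror the study
#' conditions: 100 clips per class, 4096 samples per clip at 173.61 Hz,
#' 120-order filters, 70/30 stratified split, 10 trials.
#'
#' @param clips_per_class Clips generated per class (default 100).
#' @param n_samples,fs Clip length and sampling rate.
#' @param order Filter order.
#' @param n_trials Training/evaluation trials (default 10).
#' @param split Training fraction.
#' @param lr,epochs Perceptron training parameters.
#' @param seed Master seed; every stage derives its own sub-seed from it.
#' @param device A [device_model()].
#' @param class_params Generator parameters; see [default_class_params()].
#' @param clip_dir Optional directory of plain-text clips laid out as
#'   `<class>/<clip_id>.txt`; when given, clips are read instead of
#'   generated.
#' @return A `memfir_config`.
#' @export
experiment_config <- function(clips_per_class = 100L, n_samples = 4096L,
                              fs = 173.61, order = 120L, n_trials = 10L,
                              split = 0.7, lr = 25, epochs = 2000L, seed = 1L,
                              device = device_model(),
                              class_params = default_class_params(),
                              clip_dir = NULL) {
  cfg <- list(clips_per_class = as.integer(clips_per_class),
              n_samples = as.integer(n_samples), fs = fs,
              order = as.integer(order), n_trials = as.integer(n_trials),
              split = split, lr = lr, epochs = as.integer(epochs),
              seed = as.integer(seed), device = device,
              class_params = class_params, clip_dir = clip_dir)
  validate_config(cfg)
  structure(cfg, class = "memfir_config")
}

CONFIG_KEYS <- c("clips_per_class", "n_samples", "fs", "order", "n_trials",
                 "split", "lr", "epochs", "seed", "device", "class_params",
                 "clip_dir")

validate_config <- function(cfg) {
  unknown <- setdiff(names(cfg), CONFIG_KEYS)
  if (length(unknown) > 0L) {
    stop_memfir("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  stopifnot(cfg$clips_per_class >= 1L, cfg$n_samples >= 600L,
            cfg$fs >= 60, cfg$order %% 2L == 0L, cfg$n_trials >= 2L,
            cfg$split > 0, cfg$split < 1, cfg$lr > 0, cfg$epochs >= 1L)
  invisible(cfg)
}

#' Read an experiment configuration from YAML
#'
#' Unknown keys are errors; the `device` section is passed to
#' [device_model()].
#'
#' @param path YAML file path.
#' @return A `memfir_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), CONFIG_KEYS)
  if (length(unknown) > 0L) {
    stop_memfir("unknown config keys in ", path, ": ",
                paste(unknown, collapse = ", "))
  }
  if (!is.null(raw$device)) raw$device <- do.call(device_model, raw$device)
  do.call(experiment_config, raw)
}

generate_clip_set <- function(cfg) {
  if (!is.null(cfg$clip_dir)) {
    clips <- list()
    for (cl in list.dirs(cfg$clip_dir, recursive = FALSE)) {
      label <- basename(cl)
      for (f in list.files(cl, pattern = "\\.txt$", full.names = TRUE)) {
        clips[[length(clips) + 1L]] <- read_clip_file(f, fs = cfg$fs,
                                                      label = label)
      }
    }
    if (length(clips) == 0L) stop_memfir("no clips found under ", cfg$clip_dir)
    return(clips)
  }
  clips <- vector("list", 3L * cfg$clips_per_class)
  k <- 0L
  for (label in CLASS_LABELS) {
    for (i in seq_len(cfg$clips_per_class)) {
      k <- k + 1L
      clips[[k]] <- generate_clip(
        label, n_samples = cfg$n_samples, fs = cfg$fs,
        seed = derive_seed(cfg$seed, paste0("clip_", label), i),
        class_params = cfg$class_params,
        clip_id = sprintf("%s_%03d", label, i))
    }
  }
  clips
}

#' Run the full experiment
#'
#' Generates (or reads) the clips, designs and maps the filter bank, builds
#' the S and M biomarker datasets, evaluates the S.S./M.S./M.M. modes over
#' the configured trials, computes reference-versus-crossbar error
#' statistics on a sample of segments, and produces the power report. All
#' randomness derives from the config seed, so a re-run with the same
#' config reproduces every metric.
#'
#' @param config A [experiment_config()].
#' @param out_dir Optional output directory; when given, the datasets
#'   (CSV), accuracy table (CSV) and manifest (JSON) are written there.
#' @return A `memfir_manifest` with the config snapshot, per-stage seeds,
#'   summary metrics and (in memory) the mode evaluation, error statistics
#'   and power report.
#' @export
run_experiment <- function(config = experiment_config(), out_dir = NULL) {
  validate_config(config)
  stage <- "generate clips"
  manifest_err <- function(e) {
    stop_memfir("experiment failed in stage '", stage, "': ",
                conditionMessage(e))
  }
  tryCatch({
    clips <- generate_clip_set(config)
    stage <- "filter bank design"
    bank <- build_filter_bank(default_band_specs(order = config$order,
                                                 fs = config$fs))
    stage <- "mode evaluation"
    modes <- evaluate_modes(clips, dm = config$device, bank = bank,
                            n_trials = config$n_trials,
                            seed = derive_seed(config$seed, "modes"),
                            lr = config$lr, epochs = config$epochs,
                            split = config$split)
    stage <- "error analysis"
    err <- experiment_error_stats(clips, bank, config)
    stage <- "power report"
    power <- power_report(power_assumptions(
      n_taps = config$order + 1L, v_read = config$device$v_read_max,
      g_read = config$device$g_max * 1e-6, t_read = config$device$t_read))
  }, error = manifest_err)
  manifest <- structure(
    list(
      package_version = as.character(packageVersion("memfir")),
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      config = config,
      seeds = list(master = config$seed,
                   modes = derive_seed(config$seed, "modes")),
      n_clips = length(clips),
      n_segments = nrow(modes$datasets$S),
      n_discarded = modes$datasets$n_discarded,
      n_test = nrow(modes$datasets$S) -
        sum(floor(config$split * table(modes$datasets$S$label))),
      accuracy = modes$table,
      error_stats = err,
      power = power,
      modes = modes
    ),
    class = "memfir_manifest"
  )
  if (!is.null(out_dir)) write_run_outputs(manifest, out_dir)
  manifest
}

# Reference-vs-crossbar error statistics on the first segment of a sample
# of clips (noise on), pooled across the four filters.
experiment_error_stats <- function(clips, bank, config, n_clips = 10L) {
  dm <- config$device
  pair <- program_pair(map_to_conductance(unclass(bank), dm), dm,
                       seed = derive_seed(config$seed, "err_program"))
  gmax <- max(vapply(clips, function(cl) max(abs(cl$samples)), numeric(1)))
  take <- clips[round(seq(1, length(clips), length.out = min(n_clips, length(clips))))]
  refs <- list(); mess <- list()
  for (i in seq_along(take)) {
    sg <- segment_clip(take[[i]])[[1]]
    tr <- to_voltage(sg, v_read_max = dm$v_read_max, gain = dm$v_read_max / gmax)
    refs[[i]] <- apply_bank_reference(tr$volts, bank)
    mess[[i]] <- filter_signal_crossbar(tr, pair, dm,
                                        seed = derive_seed(config$seed, "err_read", i))
  }
  error_stats(do.call(rbind, refs), do.call(rbind, mess))
}

write_run_outputs <- function(manifest, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(manifest$modes$datasets$S, file.path(out_dir, "dataset_S.csv"),
            row.names = FALSE)
  write.csv(manifest$modes$datasets$M, file.path(out_dir, "dataset_M.csv"),
            row.names = FALSE)
  write.csv(manifest$accuracy, file.path(out_dir, "accuracy.csv"),
            row.names = FALSE)
  jsonlite::write_json(report_manifest(manifest, format = "list"),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.memfir_manifest <- function(x, ...) {
  cat("<memfir_manifest>", x$created, "\n")
  cat(sprintf("  %d clips -> %d biomarker samples (%d samples discarded)\n",
              x$n_clips, x$n_segments, x$n_discarded))
  for (i in seq_len(nrow(x$accuracy))) {
    cat(sprintf("  %-5s %.2f%% +/- %.2f%%\n", x$accuracy$mode[i],
                100 * x$accuracy$mean[i], 100 * x$accuracy$sd[i]))
  }
  cat(sprintf("  filter error: pooled sigma %.3g (%.2f%% of peak-to-valley)\n",
              x$error_stats$pooled$sd, x$error_stats$pooled_sd_pct))
  cat(sprintf("  power: %.3f uW/class (memristor) vs %.1f uW/class (CMOS), %.0fx\n",
              x$power$memristor_total_uW_per_class,
              x$power$cmos_total_uW_per_class, x$power$efficiency_ratio))
  invisible(x)
}

#' Summarize a run manifest as text or a JSON-ready list
#'
#' @param manifest A `memfir_manifest` from [run_experiment()].
#' @param format `"text"` (character vector of lines), `"json"` (JSON
#'   string) or `"list"`.
#' @return Summary in the requested format.
#' @export
report_manifest <- function(manifest, format = c("text", "json", "list")) {
  format <- match.arg(format)
  base <- list(
    schema = "memfir-manifest-v1",
    package_version = manifest$package_version,
    created = manifest$created,
    seeds = manifest$seeds,
    n_clips = manifest$n_clips,
    n_segments = manifest$n_segments,
    n_discarded = manifest$n_discarded,
    accuracy = manifest$accuracy,
    error_pooled_mean = manifest$error_stats$pooled$mean,
    error_pooled_sd = manifest$error_stats$pooled$sd,
    error_pooled_sd_pct = manifest$error_stats$pooled_sd_pct,
    power = list(
      read_power_uW = manifest$power$read_power_uW,
      filter_energy_pJ_per_sample = manifest$power$filter_energy_pJ_per_sample,
      memristor_filter_uW_per_class = manifest$power$memristor_filter_uW_per_class,
      memristor_perceptron_nW_per_class = manifest$power$memristor_perceptron_nW_per_class,
      memristor_total_uW_per_class = manifest$power$memristor_total_uW_per_class,
      cmos_filter_uW_per_class = manifest$power$cmos_filter_uW_per_class,
      cmos_decoder_uW_per_class = manifest$power$cmos_decoder_uW_per_class,
      cmos_total_uW_per_class = manifest$power$cmos_total_uW_per_class,
      efficiency_ratio = manifest$power$efficiency_ratio
    )
  )
  if (format == "list") return(base)
  if (format == "json") {
    return(jsonlite::toJSON(base, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE))
  }
  c(sprintf("memfir run %s (package %s)", base$created, base$package_version),
    sprintf("clips: %d; biomarker samples: %d; discarded samples: %d",
            base$n_clips, base$n_segments, base$n_discarded),
    sprintf("%-5s %.2f%% +/- %.2f%%", base$accuracy$mode,
            100 * base$accuracy$mean, 100 * base$accuracy$sd),
    sprintf("filter error pooled sigma: %.4g (%.2f%% of peak-to-valley)",
            base$error_pooled_sd, base$error_pooled_sd_pct),
    sprintf("power: memristor %.3f uW/class, CMOS %.1f uW/class, ratio %.1fx",
            base$power$memristor_total_uW_per_class,
            base$power$cmos_total_uW_per_class,
            base$power$efficiency_ratio))
}

#' Write a small bundled clip dataset for quick end-to-end runs
#'
#' Writes `clips_per_class` generated clips per class as plain-text files
#' under `<out_dir>/<class>/<clip_id>.txt`, suitable as `clip_dir` input to
#' [experiment_config()].
#'
#' @param out_dir Target directory (created if needed).
#' @param seed Master seed.
#' @param clips_per_class Clips per class (default 6).
#' @param n_samples,fs Clip parameters.
#' @return Invisible character vector of the written file paths.
#' @export
make_fixtures <- function(out_dir, seed = 1L, clips_per_class = 6L,
                          n_samples = 4096L, fs = 173.61) {
  paths <- character(0)
  for (label in CLASS_LABELS) {
    d <- file.path(out_dir, label)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(d)) stop_memfir("cannot create ", d)
    for (i in seq_len(clips_per_class)) {
      clip <- generate_clip(label, n_samples = n_samples, fs = fs,
                            seed = derive_seed(seed, paste0("fix_", label), i),
                            clip_id = sprintf("%s_%03d", label, i))
      p <- file.path(d, paste0(clip$clip_id, ".txt"))
      write_clip_file(clip, p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
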