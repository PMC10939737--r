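#' Default end-to-end run configuration
#'
#' Analysis defaults equal the published protocol values wherever one exists:
#' 10 background scans, 1.4 V oxidation channel, 3-SD detection, 200-ms
#' assignment window, 9.8-kHz pairing tone, r2 < 0.7 exclusion. Generator
#' defaults are the simulator objects' own defaults.
#'
#' @param seed master seed; each modality derives its own sub-seed so adding
#'   a modality never perturbs the others' streams.
#' @return nested configuration list.
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    sear = list(
      enabled = TRUE,
      generator = list(),            # overrides for sear_gen_params()
      schedule = list(),             # overrides for sear_schedule()
      analysis = list(n_background = 10, detect_sd_mult = 3,
                      oxidation_voltage = 1.4, post_window = 10)),
    imaging = list(
      enabled = TRUE,
      generator = list(),            # overrides for neuron_gen_params()
      trials = list(n_repeats = 10), # demo-sized mapping session
      analysis = list(threshold = 10, window = 0.2, k_sd = 3, n_shifts = 20)),
    plasticity = list(
      enabled = TRUE,
      generator = list(n_neurons = 450, shift_fraction = 0.4),
      f_pair = 9.8),
    behavior = list(
      enabled = TRUE,
      generator = list(),            # overrides for ppi_gen_params()
      n_animals = 6,
      analysis = list(r2_threshold = 0.7)))
}

#' Read a run configuration from YAML or JSON
#'
#' Fields present in the file override [default_run_config()]; unknown keys
#' raise a validation error naming them.
#'
#' @param path YAML (.yml/.yaml) or JSON file.
#' @return configuration list.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  base <- default_run_config(seed = raw$seed %||% 1L)
  bad <- setdiff(names(raw), names(base))
  assert_that(length(bad) == 0,
              paste("unknown config keys:", paste(bad, collapse = ", ")),
              class = "acxplast_config_error")
  merge_cfg <- function(b, r) {
    for (k in names(r)) {
      b[[k]] <- if (is.list(b[[k]]) && is.list(r[[k]])) {
        merge_cfg(b[[k]], r[[k]])
      } else r[[k]]
    }
    b
  }
  merge_cfg(base, raw)
}

#' Run the full simulate-analyse-report pipeline
#'
#' Simulates every enabled modality with its sub-seed, runs the matching
#' analysis pipeline, and writes a machine-readable report bundle:
#' \code{report.json} (summary statistics, parameter-recovery comparison to
#' ground truth, configuration echo and package version) plus per-modality
#' CSV tables. Fully deterministic given (config, seed): two runs produce
#' byte-identical reports.
#'
#' @param config configuration list (see [default_run_config()] /
#'   [read_run_config()]).
#' @param outdir output directory (created if missing).
#' @return the report list, invisibly; files under \code{outdir}.
#' @export
run_end_to_end <- function(config = default_run_config(), outdir = tempdir()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  report <- list(package_version = as.character(utils::packageVersion("acxplast")),
                 seed = seed, config = config)

  if (isTRUE(config$sear$enabled)) {
    params <- do.call(sear_gen_params, config$sear$generator %||% list())
    sched <- do.call(sear_schedule, config$sear$schedule %||% list())
    gen <- generate_voltammetry_session(params, sched, seed = seed + 1L)
    ana <- do.call(analyze_sear_session,
                   c(list(session = gen$session), config$sear$analysis))
    utils::write.csv(ana$metrics, file.path(outdir, "sear_metrics.csv"),
                     row.names = FALSE)
    report$sear <- list(
      n_stimuli = nrow(sched),
      n_detected = sum(ana$metrics$detected),
      mean_latency = mean(ana$metrics$latency, na.rm = TRUE),
      mean_rise = mean(ana$metrics$rise_time, na.rm = TRUE),
      mean_decay = mean(ana$metrics$decay_time, na.rm = TRUE),
      reduction_pct = if (!is.null(ana$pairing)) ana$pairing$reduction_pct else NA,
      true_reduction_pct = 100 * (1 - params$reduction_factor),
      true_mean_latency = params$mean_latency)
  }

  if (isTRUE(config$imaging$enabled)) {
    params <- do.call(neuron_gen_params, config$imaging$generator %||% list())
    trials <- do.call(make_trial_table,
                      c(config$imaging$trials %||% list(),
                        list(seed = seed + 2L)))
    gen <- generate_roi_traces(params, trials, seed = seed + 2L)
    assert_that(params$n_neurons >= 1, "imaging requested with zero neurons",
                class = "acxplast_insufficient_data")
    tun <- do.call(run_tuning_pipeline,
                   c(list(traces = gen$traces, trials = trials),
                     config$imaging$analysis))
    tf_tab <- data.frame(roi = tun$roi_ids, tf = tun$tf,
                         responsive = tun$responsive,
                         true_tf = gen$truth$tf,
                         true_responsive = gen$truth$responsive)
    utils::write.csv(tf_tab, file.path(outdir, "imaging_tuning.csv"),
                     row.names = FALSE)
    both <- tun$responsive & gen$truth$responsive
    report$imaging <- list(
      n_neurons = params$n_neurons,
      n_responsive = sum(tun$responsive),
      responsive_fraction = mean(tun$responsive),
      true_responsive_fraction = mean(gen$truth$responsive),
      n_events = nrow(attr(tun, "events")),
      n_excluded_events = nrow(attr(tun, "excluded")),
      tf_accuracy = if (any(both)) {
        mean(tun$tf[both] == gen$truth$tf[both])
      } else NA)
  }

  if (isTRUE(config$plasticity$enabled)) {
    gen_args <- config$plasticity$generator %||% list()
    gen_args$f_pair <- config$plasticity$f_pair %||% 9.8
    exp_df <- do.call(generate_plasticity_experiment,
                      c(gen_args, list(seed = seed + 3L)))
    res <- run_plasticity_pipeline(exp_df, f_pair = gen_args$f_pair)
    utils::write.csv(res$neurons, file.path(outdir, "plasticity_neurons.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(res$heatmap),
                     file.path(outdir, "plasticity_heatmap.csv"))
    report$plasticity <- list(
      n_neurons = res$n_neurons,
      mean_delta_tf = mean(res$neurons$delta_tf),
      wilcoxon_p = res$wilcoxon$p, ks_D = res$ks$D, ks_p = res$ks$p,
      true_shift_fraction = gen_args$shift_fraction %||% 0)
  }

  if (isTRUE(config$behavior$enabled)) {
    params <- do.call(ppi_gen_params, config$behavior$generator %||% list())
    n_animals <- config$behavior$n_animals %||% 6
    fits <- lapply(seq_len(n_animals), function(a) {
      gen <- generate_ppi_session(params, seed = seed + 4L + a)
      do.call(analyze_ppi_session,
              c(list(session = gen$session), config$behavior$analysis))
    })
    tab <- data.frame(
      animal = seq_len(n_animals),
      fdt = vapply(fits, function(f) f$fdt %||% NA_real_, numeric(1)),
      r2 = vapply(fits, function(f) f$r2, numeric(1)),
      asr = vapply(fits, function(f) f$asr, numeric(1)),
      excluded = vapply(fits, function(f) f$excluded, logical(1)))
    utils::write.csv(tab, file.path(outdir, "behavior_fdt.csv"),
                     row.names = FALSE)
    report$behavior <- list(
      n_animals = n_animals, n_excluded = sum(tab$excluded),
      mean_fdt = mean(tab$fdt, na.rm = TRUE),
      true_fdt = params$true_fdt,
      mean_asr = mean(tab$asr), true_asr = params$startle_mean)
  }

  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}
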