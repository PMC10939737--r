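#' Default pure-tone stimulus frequencies (kHz)
#'
#' Eight log-spaced frequencies spanning 4.8--29.4 kHz and containing the
#' tones used in pairing and discrimination protocols (9.8, 13.9, 16.4,
#' 19.6 kHz).
#' @export
default_frequency_grid <- function() c(4.8, 6.9, 9.8, 13.9, 16.4, 19.6, 24.6, 29.4)

#' Parameters for the tone-evoked calcium-imaging simulator
#'
#' Defaults emulate jGCaMP8f recordings from layer 3/4 auditory cortex at
#' 10 frames/s: ~18\% of neurons tone-responsive, per-neuron tuning curves
#' that are Gaussian in octave distance from the tuning frequency (TF),
#' response amplitude shrinking with attenuation, fast-rise/slow-decay
#' indicator kinetics, and additive Gaussian baseline noise.
#'
#' @param n_neurons number of ROIs.
#' @param responsive_fraction probability that a neuron is tone-responsive.
#' @param tf_centers candidate TFs (kHz); responsive neurons draw from these.
#' @param tuning_width Gaussian tuning width (octaves).
#' @param transient_rise,transient_decay indicator kernel time constants (s),
#'   rise < decay.
#' @param response_amp peak dF/F (\%) at the TF, 0-dB attenuation.
#' @param amp_jitter_sdlog lognormal SD of per-trial amplitude variability.
#' @param attenuation_slope fractional amplitude loss at the largest
#'   attenuation in the trial grid (0.5 = half amplitude at 60 dB).
#' @param baseline_noise_sd additive baseline noise SD (\% dF/F).
#' @param baseline_f mean baseline fluorescence (a.u.).
#' @param plasticity_shift optional named vector mapping neuron id to a new
#'   ("after" session) TF in kHz; unlisted responsive neurons keep their TF.
#' @return object of class \code{neuron_gen_params}.
#' @export
neuron_gen_params <- function(n_neurons = 200,
                              responsive_fraction = 0.18,
                              tf_centers = default_frequency_grid(),
                              tuning_width = 0.5,
                              transient_rise = 0.02,
                              transient_decay = 0.35,
                              response_amp = 50,
                              amp_jitter_sdlog = 0.25,
                              attenuation_slope = 0.5,
                              baseline_noise_sd = 2,
                              baseline_f = 100,
                              plasticity_shift = NULL) {
  assert_that(responsive_fraction >= 0 && responsive_fraction <= 1,
              "responsive_fraction must lie in [0, 1]")
  assert_that(tuning_width > 0, "tuning_width must be positive",
              class = "acxplast_parameter_error")
  assert_that(transient_rise < transient_decay, "transient rise must be < decay")
  assert_that(baseline_noise_sd >= 0 && baseline_f > 0,
              "noise sd must be >= 0 and baseline fluorescence positive")
  structure(list(
    n_neurons = as.integer(n_neurons),
    responsive_fraction = responsive_fraction,
    tf_centers = tf_centers, tuning_width = tuning_width,
    transient_rise = transient_rise, transient_decay = transient_decay,
    response_amp = response_amp, amp_jitter_sdlog = amp_jitter_sdlog,
    attenuation_slope = attenuation_slope,
    baseline_noise_sd = baseline_noise_sd, baseline_f = baseline_f,
    plasticity_shift = plasticity_shift), class = "neuron_gen_params")
}

#' Build a pseudo-random pure-tone trial table
#'
#' Full frequency x attenuation grid, each combination repeated
#' \code{n_repeats} times (75 in a standard 30-min mapping session),
#' presented in a seeded Fisher-Yates shuffle at a fixed inter-trial
#' interval.
#'
#' @param frequencies tone frequencies (kHz).
#' @param attenuations attenuations (dB).
#' @param n_repeats repeats per combination.
#' @param iti_frames inter-trial interval (frames; 10 frames = 1 s at
#'   10 frames/s).
#' @param first_onset_frame onset frame of the first trial.
#' @param frame_rate frames per second.
#' @param seed shuffle seed.
#' @return data.frame of class \code{trial_table}: frequency, attenuation,
#'   onset_frame; grid metadata in attributes.
#' @export
make_trial_table <- function(frequencies = default_frequency_grid(),
                             attenuations = c(0, 30, 60),
                             n_repeats = 75, iti_frames = 10,
                             first_onset_frame = 51, frame_rate = 10,
                             seed = 1L) {
  grid <- expand.grid(frequency = frequencies, attenuation = attenuations,
                      KEEP.OUT.ATTRS = FALSE)
  trials <- grid[rep(seq_len(nrow(grid)), n_repeats), ]
  trials <- with_seed(seed, trials[sample.int(nrow(trials)), ])
  trials$onset_frame <- first_onset_frame +
    (seq_len(nrow(trials)) - 1L) * iti_frames
  rownames(trials) <- NULL
  structure(trials,
            frequencies = frequencies, attenuations = attenuations,
            n_repeats = n_repeats, frame_rate = frame_rate,
            iti_frames = iti_frames,
            class = c("trial_table", "data.frame"))
}

# Gaussian tuning in octave space, scaled down with attenuation
tuning_amplitude <- function(params, tf, frequency, attenuation, max_attn) {
  oct <- log2(frequency / tf)
  lvl <- 1 - params$attenuation_slope * attenuation / max(max_attn, 1)
  params$response_amp * exp(-oct^2 / (2 * params$tuning_width^2)) * lvl
}

#' Simulate ROI fluorescence traces for a tone-mapping session
#'
#' Responsive neurons emit an indicator transient (difference of
#' exponentials) after every tone, scaled by their Gaussian tuning curve and
#' the tone's attenuation, with lognormal trial-to-trial amplitude jitter;
#' non-responsive neurons carry baseline noise only. Fluorescence is returned
#' in raw arbitrary units (baseline \code{baseline_f}) so that dF/F
#' computation is part of the analysis path, not the generator.
#'
#' @param params a [neuron_gen_params()] object.
#' @param trials a [make_trial_table()] trial table.
#' @param seed integer seed; identical (params, trials, seed) give
#'   bit-identical traces.
#' @param session "before" or "after": with a non-NULL
#'   \code{params$plasticity_shift}, the "after" session uses the shifted
#'   TFs.
#' @return list(traces, truth): \code{roi_trace_set} (fluorescence matrix
#'   n_rois x n_frames, frame_rate, roi_ids) and ground truth (per-neuron
#'   responsive flag and TF; per-trial true event amplitudes and peak
#'   frames).
#' @export
generate_roi_traces <- function(params, trials = make_trial_table(),
                                seed = 1L, session = c("before", "after")) {
  stopifnot(inherits(params, "neuron_gen_params"))
  session <- match.arg(session)
  frame_rate <- attr(trials, "frame_rate") %||% 10
  max_attn <- max(attr(trials, "attenuations") %||% trials$attenuation)
  n_frames <- max(trials$onset_frame) + 10L * as.integer(frame_rate)
  n <- params$n_neurons

  # indicator kernel sampled on the frame grid (support: 5 decay constants)
  klen <- ceiling(5 * params$transient_decay * frame_rate)
  ktimes <- seq_len(klen) / frame_rate
  kern <- transient_kernel(ktimes, params$transient_rise, params$transient_decay)
  peak_off <- which.max(kern)  # frames after onset frame

  with_seed(seed, {
    responsive <- stats::runif(n) < params$responsive_fraction
    tf <- rep(NA_real_, n)
    tf[responsive] <- sample(params$tf_centers, sum(responsive), replace = TRUE)
    if (session == "after" && !is.null(params$plasticity_shift)) {
      ids <- intersect(names(params$plasticity_shift), as.character(which(responsive)))
      tf[as.integer(ids)] <- params$plasticity_shift[ids]
    }

    fmat <- matrix(stats::rnorm(n * n_frames, 0, params$baseline_noise_sd),
                   nrow = n)
    events <- vector("list", n)
    for (i in which(responsive)) {
      amps <- tuning_amplitude(params, tf[i], trials$frequency,
                               trials$attenuation, max_attn) *
        stats::rlnorm(nrow(trials), -params$amp_jitter_sdlog^2 / 2,
                      params$amp_jitter_sdlog)
      sig <- numeric(n_frames)
      for (tr in seq_len(nrow(trials))) {
        f0 <- trials$onset_frame[tr]
        idx <- f0 + seq_len(min(klen, n_frames - f0))
        sig[idx] <- sig[idx] + amps[tr] * kern[seq_along(idx)]
      }
      fmat[i, ] <- fmat[i, ] + sig
      events[[i]] <- data.frame(
        roi = i, trial = seq_len(nrow(trials)),
        onset_frame = trials$onset_frame,
        peak_frame = trials$onset_frame + peak_off,
        amplitude = amps)
    }
    fluor <- params$baseline_f * (1 + fmat / 100)

    traces <- structure(list(
      fluorescence = fluor, frame_rate = frame_rate,
      roi_ids = seq_len(n)), class = "roi_trace_set")
    truth <- structure(list(
      responsive = responsive, tf = tf,
      events = do.call(rbind, events[responsive]),
      params = params, seed = seed, session = session),
      class = "imaging_ground_truth")
    list(traces = traces, truth = truth)
  })
}
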