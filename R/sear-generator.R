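#' Parameters for the sound-evoked adenosine release (SEAR) simulator
#'
#' Defaults reproduce the statistics reported for adenosine transients in
#' mouse auditory cortex: onset latency 0.44 s with 0.17 s trial-to-trial
#' jitter, 10--90\% rise time 1.07 s (100-ms sounds) to 2.55 s (5-s sounds),
#' and 90--10\% decay time 2.41 s to 6.78 s over the same duration range.
#' Rise/decay for intermediate durations are log-interpolated between those
#' anchors. Peak amplitude grows with sound duration and falls with
#' attenuation through the two gain terms; no amplitude law is published, so
#' a simple separable law is used:
#' \code{peak = base * (1 + duration_gain * log10(dur / 0.1)) *
#'   (1 - intensity_gain * attn / 40)}.
#'
#' @param mean_latency mean transient onset latency after sound onset (s).
#' @param latency_jitter_sd SD of the per-trial latency (s), >= 0.
#' @param rise_time_by_duration,decay_time_by_duration named numeric vectors
#'   mapping sound duration (s, names) to 10--90\% rise / 90--10\% decay
#'   times (s).
#' @param peak_amp_base peak amplitude of a 100-ms, 0-dB-attenuation
#'   transient (nA for current traces; \% dF/F for sensor traces).
#' @param duration_gain dimensionless gain per decade of sound duration.
#' @param intensity_gain dimensionless gain over the 40-dB attenuation range.
#' @param noise_sd additive Gaussian noise SD, same units as amplitude.
#' @param reduction_factor multiplier in [0, 1] applied to transient
#'   amplitudes on pairing-epoch stimuli (0.415 emulates the 58.5\%
#'   reduction seen with basal-forebrain pairing).
#' @return object of class \code{sear_gen_params}.
#' @export
sear_gen_params <- function(mean_latency = 0.44,
                            latency_jitter_sd = 0.17,
                            rise_time_by_duration = c("0.1" = 1.07, "5" = 2.55),
                            decay_time_by_duration = c("0.1" = 2.41, "5" = 6.78),
                            peak_amp_base = 1.0,
                            duration_gain = 0.5,
                            intensity_gain = 0.5,
                            noise_sd = 0.02,
                            reduction_factor = 0.415) {
  assert_that(latency_jitter_sd >= 0, "latency_jitter_sd must be >= 0")
  assert_that(all(rise_time_by_duration > 0) && all(decay_time_by_duration > 0),
              "rise and decay times must be positive")
  assert_that(reduction_factor >= 0 && reduction_factor <= 1,
              "reduction_factor must lie in [0, 1]")
  assert_that(noise_sd >= 0, "noise_sd must be >= 0")
  assert_that(peak_amp_base > 0, "peak_amp_base must be positive")
  structure(list(
    mean_latency = mean_latency, latency_jitter_sd = latency_jitter_sd,
    rise_time_by_duration = rise_time_by_duration,
    decay_time_by_duration = decay_time_by_duration,
    peak_amp_base = peak_amp_base, duration_gain = duration_gain,
    intensity_gain = intensity_gain, noise_sd = noise_sd,
    reduction_factor = reduction_factor), class = "sear_gen_params")
}

# amplitude law (documented in sear_gen_params)
sear_amplitude <- function(params, duration, attenuation) {
  params$peak_amp_base *
    (1 + params$duration_gain * log10(duration / 0.1)) *
    (1 - params$intensity_gain * attenuation / 40)
}

sear_kinetics_for_duration <- function(params, duration) {
  rd <- params$rise_time_by_duration
  dd <- params$decay_time_by_duration
  list(rise = loglin_interp(duration, as.numeric(names(rd)), rd),
       decay = loglin_interp(duration, as.numeric(names(dd)), dd))
}

#' Build a stimulus schedule for an FSCV pairing session
#'
#' Baseline, pairing and post epochs of broadband-noise presentations at a
#' fixed inter-stimulus interval (60 s by default, as in repeated SEAR
#' sessions; pairing rounds at ~0.016 Hz).
#'
#' @param n_baseline,n_pairing,n_post stimuli per epoch.
#' @param interval inter-onset interval (s).
#' @param duration sound duration (s).
#' @param attenuation attenuation re max level (dB).
#' @param first_onset onset of the first stimulus (s).
#' @return data.frame with columns onset, duration, attenuation, epoch.
#' @export
sear_schedule <- function(n_baseline = 5, n_pairing = 5, n_post = 5,
                          interval = 60, duration = 5, attenuation = 0,
                          first_onset = 30) {
  n <- n_baseline + n_pairing + n_post
  data.frame(
    onset = first_onset + (seq_len(n) - 1) * interval,
    duration = duration,
    attenuation = attenuation,
    epoch = rep(c("baseline", "pairing", "post"),
                c(n_baseline, n_pairing, n_post)),
    stringsAsFactors = FALSE)
}

#' Simulate a fast-scan cyclic voltammetry session with SEAR transients
#'
#' Produces a scan-by-sample current matrix for a triangular waveform
#' (-0.4 to 1.5 V and back at 400 V/s, one scan per 100 ms). Each scheduled
#' stimulus adds an adenosine oxidation transient: a gamma-pulse time course
#' whose kinetics follow the stimulus duration, whose amplitude follows the
#' duration/attenuation law, and whose voltammogram signature is a Gaussian
#' bump in voltage centred on 1.4 V. A stable per-sample background current
#' underlies every scan; additive Gaussian noise is added throughout.
#' Pairing-epoch transients are scaled by \code{params$reduction_factor}.
#'
#' @param params a [sear_gen_params()] object.
#' @param stimuli stimulus schedule data.frame (see [sear_schedule()]).
#' @param seed integer seed; identical (params, stimuli, seed) give
#'   bit-identical sessions.
#' @param session_length session length (s); default covers the schedule
#'   plus a 30-s tail.
#' @param scan_period scan repetition period (s).
#' @param sample_hz within-scan ADC rate (Hz); the default 20 kHz puts the
#'   1.4-V oxidation voltage exactly on an ascending-sweep sample.
#' @param onset_anchor_sd_mult detection-level convention anchoring each
#'   transient's latency: the pulse is shifted so it crosses
#'   \code{onset_anchor_sd_mult * noise_sd} above baseline exactly at
#'   onset + latency, matching the threshold-crossing definition of latency
#'   used by [transient_metrics()]. With \code{noise_sd = 0} the anchor is
#'   the pulse foot.
#' @return list(session, truth): a \code{voltammetry_session} object and a
#'   ground-truth record (one row per stimulus: latency, amplitude, pulse
#'   shape, epoch).
#' @export
generate_voltammetry_session <- function(params, stimuli = sear_schedule(),
                                         seed = 1L,
                                         session_length = NULL,
                                         scan_period = 0.1,
                                         sample_hz = 20000,
                                         onset_anchor_sd_mult = 3) {
  stopifnot(inherits(params, "sear_gen_params"))
  assert_that(nrow(stimuli) >= 1, "stimulus schedule is empty")
  assert_that(!is.unsorted(stimuli$onset, strictly = TRUE),
              "stimulus onsets must be strictly increasing")
  if (nrow(stimuli) > 1) {
    assert_that(all(diff(stimuli$onset) > scan_period),
                "stimuli closer than the scan period: schedule rejected")
  }
  session_length <- session_length %||%
    (max(stimuli$onset + stimuli$duration) + 30)
  assert_that(max(stimuli$onset) < session_length,
              "stimulus onsets must fall within the session")

  wf <- scan_waveform(scan_period = scan_period, sample_hz = sample_hz)
  n_scans <- floor(session_length / scan_period)
  scan_time <- (seq_len(n_scans) - 1) * scan_period

  # stable background: smooth capacitive-looking profile, identical per scan
  bg <- 40 + 25 * sin(2 * pi * seq_len(wf$n_samples) / wf$n_samples) +
    10 * wf$voltage
  # voltammogram signature of the adenosine oxidation peak (unit at 1.4 V)
  vsig <- exp(-(wf$voltage - 1.4)^2 / (2 * 0.08^2))

  with_seed(seed, {
    lat <- stats::rnorm(nrow(stimuli), params$mean_latency,
                        params$latency_jitter_sd)
    lat <- pmax(lat, 0)
    truth <- data.frame(
      stimulus = seq_len(nrow(stimuli)),
      onset = stimuli$onset, duration = stimuli$duration,
      attenuation = stimuli$attenuation, epoch = stimuli$epoch,
      latency = lat, transient_onset = stimuli$onset + lat,
      amplitude = NA_real_, rise = NA_real_, decay = NA_real_,
      shape = NA_real_, pulse_peak_time = NA_real_,
      stringsAsFactors = FALSE)

    signal <- numeric(n_scans) # oxidation-channel time course, noiseless
    for (i in seq_len(nrow(stimuli))) {
      kin <- sear_kinetics_for_duration(params, stimuli$duration[i])
      sh <- solve_pulse_shape(kin$rise, kin$decay)
      amp <- sear_amplitude(params, stimuli$duration[i], stimuli$attenuation[i])
      if (identical(stimuli$epoch[i], "pairing")) amp <- amp * params$reduction_factor
      truth$amplitude[i] <- amp
      truth$rise[i] <- kin$rise; truth$decay[i] <- kin$decay
      truth$shape[i] <- sh$shape; truth$pulse_peak_time[i] <- sh$peak_time
      # latency is operational: the transient is placed so that its
      # detectable rise (crossing of onset_anchor_sd_mult x noise_sd above
      # baseline) occurs at onset + latency; with zero noise this reduces
      # to the pulse foot.
      frac <- min(0.5, onset_anchor_sd_mult * params$noise_sd / amp)
      t_anchor <- pulse_threshold_time(sh$shape, sh$peak_time, frac)
      signal <- signal + amp *
        gamma_pulse(scan_time - (truth$transient_onset[i] - t_anchor),
                    sh$shape, sh$peak_time)
    }

    currents <- matrix(rep(bg, each = n_scans), nrow = n_scans) +
      outer(signal, vsig)
    if (params$noise_sd > 0) {
      currents <- currents +
        matrix(stats::rnorm(length(currents), 0, params$noise_sd),
               nrow = n_scans)
    }

    session <- structure(list(
      currents = currents, waveform = wf, scan_period = scan_period,
      time = scan_time, stimuli = stimuli, background = bg,
      voltage_signature = vsig), class = "voltammetry_session")
    truth <- structure(list(events = truth, params = params, seed = seed,
                            signal = signal),
                       class = "sear_ground_truth")
    list(session = session, truth = truth)
  })
}

#' Triangular FSCV scan waveform
#'
#' Voltage of each ADC sample within one scan: \code{v_min} to \code{v_max}
#' and back at \code{scan_rate}, sampled at \code{sample_hz}. The first half
#' of the samples is the ascending sweep.
#'
#' @param v_min,v_max sweep limits (V).
#' @param scan_rate sweep rate (V/s).
#' @param scan_period scan repetition period (s); only used for validation.
#' @param sample_hz ADC rate (Hz).
#' @return list with \code{voltage} (per-sample V), \code{ascending}
#'   (logical), \code{n_samples}, and the waveform parameters.
#' @export
scan_waveform <- function(v_min = -0.4, v_max = 1.5, scan_rate = 400,
                          scan_period = 0.1, sample_hz = 20000) {
  sweep_s <- (v_max - v_min) / scan_rate        # one-way sweep duration
  assert_that(2 * sweep_s <= scan_period,
              "round-trip sweep does not fit in the scan period")
  n_half <- round(sweep_s * sample_hz)
  dv <- (v_max - v_min) / n_half
  v_up <- v_min + (seq_len(n_half) - 1) * dv
  v_down <- v_max - (seq_len(n_half) - 1) * dv
  list(voltage = c(v_up, v_down),
       ascending = rep(c(TRUE, FALSE), each = n_half),
       n_samples = 2L * n_half,
       v_min = v_min, v_max = v_max, scan_rate = scan_rate,
       sample_hz = sample_hz)
}
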