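#' Per-stimulus background subtraction of a voltammetry session
#'
#' For each scheduled stimulus, the mean of the \code{n_background} scans
#' immediately preceding its onset is subtracted from every scan in that
#' stimulus's analysis window. The analysis window runs from the first
#' background scan to \code{onset + duration + post_window}; scans outside
#' every window are left untouched, so the result is aligned to the original
#' time axis. Because the background scans themselves lie inside the window,
#' re-running the subtraction on a stable-background session is a no-op.
#'
#' @param session a \code{voltammetry_session}.
#' @param n_background number of pre-onset scans to average (10, as in
#'   flow-cell calibration practice).
#' @param post_window seconds of post-stimulus data included in each
#'   stimulus's analysis window (the peak window for long sounds is an open
#'   methodological point; onset + duration + 10 s is the default).
#' @return the session with \code{currents} background-subtracted inside the
#'   per-stimulus windows and a \code{windows} data.frame (scan index ranges)
#'   attached.
#' @export
background_subtract <- function(session, n_background = 10, post_window = 10) {
  stopifnot(inherits(session, "voltammetry_session"))
  cur <- session$currents
  period <- session$scan_period
  windows <- data.frame(stimulus = integer(), first = integer(), last = integer())
  for (i in seq_len(nrow(session$stimuli))) {
    onset <- session$stimuli$onset[i]
    onset_scan <- floor(onset / period + 1e-9) + 1L  # first scan at/after onset
    bg_first <- onset_scan - n_background
    assert_that(bg_first >= 1, sprintf(
      "stimulus %d at %.3f s: fewer than %d pre-stimulus scans available",
      i, onset, n_background), class = "acxplast_window_error")
    # one extra scan of margin so the metrics window never outruns the
    # subtracted region through rounding
    last <- min(nrow(cur),
                floor((onset + session$stimuli$duration[i] + post_window) /
                        period + 1e-9) + 2L)
    bg <- colMeans(session$currents[bg_first:(onset_scan - 1L), , drop = FALSE])
    idx <- bg_first:last
    cur[idx, ] <- sweep(session$currents[idx, , drop = FALSE], 2L, bg)
    windows <- rbind(windows,
                     data.frame(stimulus = i, first = bg_first, last = last))
  }
  out <- session
  out$currents <- cur
  out$windows <- windows
  out$background_subtracted <- TRUE
  out
}

#' Extract the adenosine oxidation-channel trace
#'
#' Returns, per scan, the current at the ascending-sweep sample whose applied
#' potential is nearest the adenosine oxidation voltage (1.4 V).
#'
#' @param session a (typically background-subtracted) \code{voltammetry_session}.
#' @param oxidation_voltage target potential (V); must lie within the
#'   ascending sweep.
#' @return data.frame with \code{time} (s), \code{current}, and the sample
#'   index used (attribute \code{"sample"}).
#' @export
extract_oxidation_trace <- function(session, oxidation_voltage = 1.4) {
  stopifnot(inherits(session, "voltammetry_session"))
  wf <- session$waveform
  assert_that(oxidation_voltage >= wf$v_min && oxidation_voltage <= wf$v_max,
              "oxidation voltage lies outside the sweep range",
              class = "acxplast_range_error")
  up <- which(wf$ascending)
  j <- up[which.min(abs(wf$voltage[up] - oxidation_voltage))]
  out <- data.frame(time = session$time, current = session$currents[, j])
  attr(out, "sample") <- j
  attr(out, "voltage") <- wf$voltage[j]
  out
}

#' Fit an adenosine calibration line
#'
#' Averages replicate peak currents per concentration and fits an ordinary
#' least-squares line current ~ concentration (flow-cell calibration with
#' 3 replicates per point, concentrations 0.1--5 uM in practice).
#'
#' @param concentrations concentration of each replicate measurement (uM).
#' @param peak_currents replicate peak currents (nA), same length.
#' @return object of class \code{calibration_curve}: slope (nA/uM),
#'   intercept (nA), r2, per-concentration means, replicate counts, and a
#'   \code{usable} flag (FALSE when the line carries no information,
#'   slope == 0).
#' @export
fit_calibration <- function(concentrations, peak_currents) {
  assert_that(length(concentrations) == length(peak_currents),
              "concentrations and peak_currents differ in length")
  conc <- sort(unique(concentrations))
  assert_that(length(conc) >= 2,
              "need at least 2 distinct concentrations for a calibration line",
              class = "acxplast_singular_fit")
  means <- vapply(conc, function(cc) mean(peak_currents[concentrations == cc]),
                  numeric(1))
  n_rep <- vapply(conc, function(cc) sum(concentrations == cc), integer(1))
  fit <- stats::lm(means ~ conc)
  ss_tot <- sum((means - mean(means))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  slope <- unname(stats::coef(fit)[2])
  flat <- abs(slope) < 1e-10 * max(abs(means), 1)
  if (flat) slope <- 0
  structure(list(
    concentrations = conc, mean_peak_currents = means, n_replicates = n_rep,
    slope = slope, intercept = unname(stats::coef(fit)[1]),
    r2 = r2, usable = !flat), class = "calibration_curve")
}

#' Convert a current trace to concentration via a calibration curve
#'
#' @param trace numeric current series (nA) or a data.frame with a
#'   \code{current} column.
#' @param cal a \code{calibration_curve}.
#' @return concentrations (uM), same shape as the input.
#' @export
current_to_concentration <- function(trace, cal) {
  stopifnot(inherits(cal, "calibration_curve"))
  assert_that(cal$slope != 0, "calibration slope is zero; cannot invert",
              class = "acxplast_singular_fit")
  if (is.data.frame(trace)) {
    trace$concentration <- (trace$current - cal$intercept) / cal$slope
    trace
  } else {
    (trace - cal$intercept) / cal$slope
  }
}

#' Transient detection and kinetic metrics on a 1-D trace
#'
#' Detection: first post-onset crossing of baseline mean + \code{detect_sd_mult}
#' x baseline SD (baseline = the \code{baseline_s} seconds preceding onset).
#' Latency is the interpolated crossing time minus onset. The peak is the
#' maximum within \code{(onset, onset + duration + post_window]}; rise is the
#' interpolated 10\% to 90\% time on the ascending limb, decay the 90\% to
#' 10\% time on the descending limb (amplitudes relative to the baseline
#' mean). Returns \code{NULL} when no threshold crossing occurs.
#'
#' @param trace data.frame(time, current-like value) or numeric vector (then
#'   \code{time} must be given).
#' @param stimulus_onset onset time (s).
#' @param duration stimulus duration (s), used for the analysis window.
#' @param detect_sd_mult detection threshold in baseline SDs.
#' @param post_window analysis window extension past stimulus offset (s).
#' @param baseline_s length of the pre-onset baseline (s); at least 1 s of
#'   pre-onset data is required.
#' @param time optional time vector when \code{trace} is numeric.
#' @return list of class \code{transient_metrics} (peak_amp, peak_time,
#'   latency, rise_time, decay_time, threshold) or \code{NULL}.
#' @export
transient_metrics <- function(trace, stimulus_onset, duration = 5,
                              detect_sd_mult = 3, post_window = 10,
                              baseline_s = 1, time = NULL) {
  if (is.data.frame(trace)) {
    time <- trace$time
    y <- trace[[setdiff(names(trace), "time")[1]]]
  } else {
    y <- trace
    assert_that(!is.null(time), "numeric trace requires a time vector")
  }
  assert_that(time[1] <= stimulus_onset - baseline_s,
              "trace must contain at least the requested pre-onset baseline")
  w_end <- stimulus_onset + duration + post_window
  assert_that(max(time) >= w_end,
              "analysis window extends past the end of the trace",
              class = "acxplast_window_error")

  base_idx <- which(time >= stimulus_onset - baseline_s & time < stimulus_onset)
  b_mean <- mean(y[base_idx])
  b_sd <- stats::sd(y[base_idx])
  thr <- b_mean + detect_sd_mult * b_sd

  win <- which(time > stimulus_onset & time <= w_end)
  # detection requires strictly exceeding the threshold (a noiseless
  # baseline sits exactly at it); the crossing time is then interpolated
  above <- win[y[win] > thr]
  if (!length(above)) return(NULL)
  k <- above[1]
  cross_t <- if (k == win[1] || y[k - 1L] >= thr) {
    time[max(k - 1L, win[1])]
  } else {
    time[k - 1L] + (thr - y[k - 1L]) / (y[k] - y[k - 1L]) *
      (time[k] - time[k - 1L])
  }

  ipk <- win[which.max(y[win])]
  peak_amp <- y[ipk] - b_mean
  if (peak_amp <= 0) return(NULL)

  lev <- function(frac) b_mean + frac * peak_amp
  # ascending limb: last upward crossings before the peak
  t10 <- last_crossing_up(time, y, lev(0.1), win[1], ipk)
  t90 <- last_crossing_up(time, y, lev(0.9), win[1], ipk)
  # descending limb: first downward crossings after the peak
  d90 <- crossing_time(time, y, lev(0.9), ipk, win[length(win)], direction = -1L)
  d10 <- crossing_time(time, y, lev(0.1), ipk, win[length(win)], direction = -1L)

  structure(list(
    peak_amp = peak_amp, peak_time = time[ipk],
    latency = cross_t - stimulus_onset,
    rise_time = if (is.na(t10) || is.na(t90)) NA_real_ else t90 - t10,
    decay_time = if (is.na(d10) || is.na(d90)) NA_real_ else d10 - d90,
    threshold = thr, baseline_mean = b_mean, baseline_sd = b_sd),
    class = "transient_metrics")
}

# interpolated time of the last upward crossing of `level` in i0:i1
last_crossing_up <- function(t, y, level, i0, i1) {
  idx <- seq.int(i0, i1)
  below <- which(y[idx] < level)
  if (!length(below)) return(t[idx[1]])
  k <- below[length(below)]
  if (idx[k] >= i1) return(NA_real_)
  ia <- idx[k]; ib <- idx[k] + 1L
  if (y[ib] == y[ia]) return(t[ib])
  t[ia] + (level - y[ia]) / (y[ib] - y[ia]) * (t[ib] - t[ia])
}

#' Pairing-epoch SEAR reduction
#'
#' Normalizes per-trial peak amplitudes to the baseline-epoch mean (= 100\%)
#' and reports the percentage reduction during the pairing epoch, with a
#' paired comparison across recordings (two-tailed paired t test when the
#' per-recording baseline-pairing differences pass Shapiro-Wilk normality at
#' alpha = 0.05, Wilcoxon signed-rank otherwise).
#'
#' @param peaks data.frame with columns \code{peak} (amplitude), \code{epoch}
#'   (\code{"baseline"}, \code{"pairing"}, \code{"post"}) and optionally
#'   \code{recording} (defaults to a single recording).
#' @return object of class \code{pairing_result}: normalized per-trial peaks,
#'   epoch means +/- SEM, \code{reduction_pct}, and the paired test.
#' @export
pairing_reduction <- function(peaks) {
  stopifnot(is.data.frame(peaks), all(c("peak", "epoch") %in% names(peaks)))
  if (is.null(peaks$recording)) peaks$recording <- 1L
  assert_that(sum(peaks$epoch == "baseline") >= 3,
              "need at least 3 baseline trials")
  assert_that(sum(peaks$epoch == "pairing") >= 1,
              "need at least 1 pairing trial")

  peaks$normalized <- NA_real_
  for (r in unique(peaks$recording)) {
    sel <- peaks$recording == r
    b <- mean(peaks$peak[sel & peaks$epoch == "baseline"])
    assert_that(is.finite(b) && b > 0,
                sprintf("recording %s: baseline mean is not positive", r),
                class = "acxplast_normalization_error")
    peaks$normalized[sel] <- 100 * peaks$peak[sel] / b
  }

  epochs <- c("baseline", "pairing", "post")
  epoch_mean <- vapply(epochs, function(e) {
    v <- peaks$normalized[peaks$epoch == e]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  epoch_sem <- vapply(epochs, function(e) {
    v <- peaks$normalized[peaks$epoch == e]
    if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  }, numeric(1))
  reduction_pct <- 100 - epoch_mean[["pairing"]]

  recs <- unique(peaks$recording)
  test <- list(method = NA_character_, statistic = NA_real_, p = NA_real_)
  if (length(recs) >= 3) {
    bmeans <- vapply(recs, function(r) mean(
      peaks$peak[peaks$recording == r & peaks$epoch == "baseline"]), numeric(1))
    pmeans <- vapply(recs, function(r) mean(
      peaks$peak[peaks$recording == r & peaks$epoch == "pairing"]), numeric(1))
    d <- bmeans - pmeans
    if (all(d == 0)) {
      test <- list(method = "degenerate (no difference)", statistic = 0, p = 1)
      return(structure(list(trials = peaks, epoch_mean = epoch_mean,
                            epoch_sem = epoch_sem,
                            reduction_pct = reduction_pct, test = test),
                       class = "pairing_result"))
    }
    normal_ok <- length(d) >= 3 && length(unique(d)) > 1 &&
      stats::shapiro.test(d)$p.value >= 0.05
    if (normal_ok) {
      tt <- stats::t.test(bmeans, pmeans, paired = TRUE)
      test <- list(method = "paired t", statistic = unname(tt$statistic),
                   p = tt$p.value)
    } else {
      wt <- suppressWarnings(stats::wilcox.test(bmeans, pmeans, paired = TRUE))
      test <- list(method = "wilcoxon signed-rank",
                   statistic = unname(wt$statistic), p = wt$p.value)
    }
  }

  structure(list(trials = peaks, epoch_mean = epoch_mean,
                 epoch_sem = epoch_sem, reduction_pct = reduction_pct,
                 test = test), class = "pairing_result")
}

#' Correlate paired responses from two measurement modalities
#'
#' Least-squares line and r-squared between paired responses (e.g., FSCV peak
#' currents vs fluorescence-sensor responses at matched adenosine
#' concentrations).
#'
#' @param x,y paired responses, length >= 3.
#' @return list(r2, slope, intercept, p, n).
#' @export
correlate_modalities <- function(x, y) {
  assert_that(length(x) == length(y), "x and y must be paired")
  assert_that(length(x) >= 3, "need at least 3 paired points")
  fit <- stats::lm(y ~ x)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  n <- length(x)
  # two-sided p for the slope via the t distribution of the correlation
  r2c <- min(r2, 1 - 1e-15)
  tval <- sqrt(r2c * (n - 2) / (1 - r2c))
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  list(r2 = r2, slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), p = p, n = n)
}

#' Full SEAR session analysis
#'
#' Background subtraction, oxidation-channel extraction, per-stimulus
#' transient metrics, and pairing-epoch reduction in one call.
#'
#' @param session a \code{voltammetry_session}.
#' @param n_background,post_window,detect_sd_mult,oxidation_voltage see the
#'   stage functions.
#' @return list with the subtracted session, the oxidation \code{trace}, a
#'   per-stimulus \code{metrics} data.frame, and the \code{pairing}
#'   [pairing_reduction()] result (NULL when the schedule has no pairing
#'   epoch).
#' @export
analyze_sear_session <- function(session, n_background = 10, post_window = 10,
                                 detect_sd_mult = 3, oxidation_voltage = 1.4) {
  sub <- background_subtract(session, n_background = n_background,
                             post_window = post_window)
  trace <- extract_oxidation_trace(sub, oxidation_voltage = oxidation_voltage)
  rows <- lapply(seq_len(nrow(session$stimuli)), function(i) {
    m <- transient_metrics(trace, session$stimuli$onset[i],
                           duration = session$stimuli$duration[i],
                           detect_sd_mult = detect_sd_mult,
                           post_window = post_window)
    data.frame(stimulus = i, epoch = session$stimuli$epoch[i],
               detected = !is.null(m),
               peak = if (is.null(m)) NA_real_ else m$peak_amp,
               latency = if (is.null(m)) NA_real_ else m$latency,
               rise_time = if (is.null(m)) NA_real_ else m$rise_time,
               decay_time = if (is.null(m)) NA_real_ else m$decay_time,
               stringsAsFactors = FALSE)
  })
  metrics <- do.call(rbind, rows)
  pairing <- NULL
  if (any(metrics$epoch == "pairing") &&
      sum(metrics$epoch == "baseline" & metrics$detected) >= 3) {
    det <- metrics[metrics$detected, c("peak", "epoch")]
    pairing <- pairing_reduction(det)
  }
  list(session = sub, trace = trace, metrics = metrics, pairing = pairing)
}
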