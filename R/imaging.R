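#' Compute dF/F (\%) from raw ROI fluorescence
#'
#' Per ROI, the baseline F0 is a low percentile of that ROI's own trace
#' (20th by default — robust to sparse transients riding on a stable
#' baseline); output is \code{(F - F0) / F0 * 100} per frame. ROIs whose F0
#' is not positive are flagged invalid and returned as NA rows.
#'
#' @param traces a \code{roi_trace_set} (list with \code{fluorescence}
#'   matrix n_rois x n_frames, \code{frame_rate}, \code{roi_ids}) or a bare
#'   matrix.
#' @param baseline_percentile percentile (0--100) defining F0.
#' @return matrix of dF/F in \%, same shape, with attributes \code{f0} and
#'   \code{invalid} (logical per ROI).
#' @export
compute_dff <- function(traces, baseline_percentile = 20) {
  fmat <- if (inherits(traces, "roi_trace_set")) traces$fluorescence else traces
  stopifnot(is.matrix(fmat))
  f0 <- apply(fmat, 1L, stats::quantile, probs = baseline_percentile / 100,
              names = FALSE)
  invalid <- !is.finite(f0) | f0 <= 0
  dff <- (fmat - f0) / f0 * 100
  dff[invalid, ] <- NA_real_
  attr(dff, "f0") <- f0
  attr(dff, "invalid") <- invalid
  dff
}

#' Detect calcium transient peaks with kinetics screening
#'
#' All strict local maxima of each ROI's dF/F trace exceeding
#' \code{threshold} are candidate events; each candidate's interpolated
#' 10--90\% rise (measured backwards from the peak) and 90--10\% decay
#' (forwards) must fall within indicator-like bounds (jGCaMP8f defaults:
#' rise <= 0.3 s, decay 0.1--2 s) or the candidate is discarded.
#'
#' @param dff dF/F matrix (\%, ROIs x frames) from [compute_dff()], or a
#'   numeric vector for a single ROI.
#' @param frame_rate frames per second.
#' @param threshold minimum peak amplitude (\% dF/F), > 0.
#' @param rise_max maximum 10--90\% rise time (s).
#' @param decay_range allowed 90--10\% decay time range (s), length 2.
#' @return data.frame of events sorted by frame: roi, frame, amplitude,
#'   rise_time, decay_time, rise_ok, decay_ok (all returned events pass both
#'   screens).
#' @export
detect_peaks <- function(dff, frame_rate = 10, threshold = 10,
                         rise_max = 0.3, decay_range = c(0.1, 2)) {
  assert_that(threshold > 0, "threshold must be positive")
  assert_that(rise_max > 0 && all(decay_range > 0) && length(decay_range) == 2,
              "kinetics bounds must be positive")
  if (is.null(dim(dff))) dff <- matrix(dff, nrow = 1L)
  min_len <- ceiling((rise_max + max(decay_range)) * frame_rate) + 2L
  assert_that(ncol(dff) >= min_len,
              "trace shorter than the kinetics measurement window")
  out <- vector("list", nrow(dff))
  tt <- (seq_len(ncol(dff)) - 1L) / frame_rate
  for (r in seq_len(nrow(dff))) {
    y <- dff[r, ]
    if (anyNA(y)) next
    n <- length(y)
    cand <- which(y > threshold &
                    y > c(-Inf, y[-n]) &      # strictly above left neighbour
                    y >= c(y[-1], -Inf))      # at least right neighbour
    if (!length(cand)) next
    keep <- logical(length(cand))
    rises <- decays <- numeric(length(cand))
    for (k in seq_along(cand)) {
      i <- cand[k]
      amp <- y[i]
      # search limits: previous/next sub-10% trough or neighbouring candidate
      lo <- max(1L, i - ceiling(2 * rise_max * frame_rate) - 2L)
      hi <- min(n, i + ceiling(2 * max(decay_range) * frame_rate) + 2L)
      t10 <- last_crossing_up(tt, y, 0.1 * amp, lo, i)
      t90 <- last_crossing_up(tt, y, 0.9 * amp, lo, i)
      d90 <- crossing_time(tt, y, 0.9 * amp, i, hi, direction = -1L)
      d10 <- crossing_time(tt, y, 0.1 * amp, i, hi, direction = -1L)
      rise <- if (is.na(t10) || is.na(t90)) NA_real_ else t90 - t10
      decay <- if (is.na(d10) || is.na(d90)) NA_real_ else d10 - d90
      rises[k] <- rise; decays[k] <- decay
      keep[k] <- !is.na(rise) && !is.na(decay) &&
        rise <= rise_max &&
        decay >= decay_range[1] && decay <= decay_range[2]
    }
    if (any(keep)) {
      out[[r]] <- data.frame(
        roi = r, frame = cand[keep], amplitude = y[cand[keep]],
        rise_time = rises[keep], decay_time = decays[keep],
        rise_ok = TRUE, decay_ok = TRUE)
    }
  }
  ev <- do.call(rbind, out)
  if (is.null(ev)) {
    ev <- data.frame(roi = integer(), frame = integer(), amplitude = numeric(),
                     rise_time = numeric(), decay_time = numeric(),
                     rise_ok = logical(), decay_ok = logical())
  }
  ev[order(ev$roi, ev$frame), , drop = FALSE]
}

#' Assign detected peaks to tone trials (200-ms rule)
#'
#' A peak is sound-related only if it falls within \code{window} seconds
#' after a tone onset; each such event is assigned to the nearest preceding
#' trial, and all other events are excluded with a logged reason.
#'
#' @param events event data.frame from [detect_peaks()].
#' @param trials a [make_trial_table()] trial table (onset_frame strictly
#'   increasing).
#' @param window assignment window (s) after tone onset; 0.2 s by default.
#' @param frame_rate frames per second (taken from the trial table when
#'   present).
#' @return list(assigned, excluded): \code{assigned} has the trial index and
#'   its frequency/attenuation appended; \code{excluded} carries a
#'   \code{reason} column. Every input event appears in exactly one of the
#'   two.
#' @export
assign_peaks_to_stimuli <- function(events, trials, window = 0.2,
                                    frame_rate = NULL) {
  frame_rate <- frame_rate %||% attr(trials, "frame_rate") %||% 10
  win_frames <- window * frame_rate
  empty_assigned <- cbind(events[0, , drop = FALSE],
                          data.frame(trial = integer(), frequency = numeric(),
                                     attenuation = numeric()))
  if (nrow(trials) == 0) {
    excl <- events
    excl$reason <- rep("no trials", nrow(events))
    return(list(assigned = empty_assigned, excluded = excl))
  }
  assert_that(!is.unsorted(trials$onset_frame, strictly = TRUE),
              "trial onsets must be strictly increasing")
  if (nrow(trials) > 1) {
    assert_that(min(diff(trials$onset_frame)) >= win_frames,
                "inter-trial interval shorter than the assignment window",
                class = "acxplast_schedule_error")
  }
  if (nrow(events) == 0) {
    excl <- events; excl$reason <- character(0)
    return(list(assigned = empty_assigned, excluded = excl))
  }
  prev <- findInterval(events$frame - 1e-9, trials$onset_frame)
  lag <- events$frame - ifelse(prev >= 1, trials$onset_frame[pmax(prev, 1L)], Inf)
  ok <- prev >= 1 & lag > 0 & lag <= win_frames
  assigned <- events[ok, , drop = FALSE]
  if (nrow(assigned)) {
    assigned$trial <- prev[ok]
    assigned$frequency <- trials$frequency[prev[ok]]
    assigned$attenuation <- trials$attenuation[prev[ok]]
  } else {
    assigned <- empty_assigned
  }
  excluded <- events[!ok, , drop = FALSE]
  excluded$reason <- rep("outside 200-ms window", sum(!ok))
  list(assigned = assigned, excluded = excluded)
}

#' Flag saturated ROIs
#'
#' An indicator-saturated (clipped) cell spends many frames pinned at the top
#' of its own dynamic range, whereas a healthy cell touches its maximum only
#' at isolated transient peaks. An ROI is flagged when more than
#' \code{max_fraction} of its frames lie within \code{ceiling_fraction} of
#' its own maximum fluorescence.
#'
#' @param traces a \code{roi_trace_set} or fluorescence matrix.
#' @param ceiling_fraction fraction of the ROI's maximum defining "at
#'   ceiling" (0.999).
#' @param max_fraction maximal tolerated fraction of at-ceiling frames (0.01).
#' @return logical vector per ROI.
#' @export
flag_saturated <- function(traces, ceiling_fraction = 0.999, max_fraction = 0.01) {
  fmat <- if (inherits(traces, "roi_trace_set")) traces$fluorescence else traces
  ceiling_f <- ceiling_fraction * apply(fmat, 1L, max)
  rowMeans(fmat >= ceiling_f) > max_fraction
}

#' Build per-neuron tuning results from assigned events
#'
#' Each ROI's response matrix holds the mean assigned-event amplitude per
#' frequency x attenuation combination over the full declared repeat count
#' (trials without an event contribute 0, keeping a fixed denominator). The
#' tuning frequency (TF) is the frequency maximizing the across-attenuation
#' mean response, ties broken to the lower frequency. Responsiveness is
#' gated on a within-ROI trial-shuffled null: event frames are circularly
#' shifted (deterministic offsets), reassigned, and the observed response
#' matrix must exceed \code{null mean + k_sd x null SD} in at least one cell.
#'
#' @param assigned assigned-event data.frame from [assign_peaks_to_stimuli()].
#' @param trials the trial table used for assignment.
#' @param roi_ids all ROI ids (including ROIs with no events).
#' @param n_frames session length in frames (for circular shifts).
#' @param k_sd responsiveness threshold in null SDs (3).
#' @param n_shifts number of circular shifts building the null (20).
#' @param saturated optional logical per ROI from [flag_saturated()];
#'   saturated ROIs are rejected (no TF, not responsive).
#' @param window,frame_rate assignment parameters, as in
#'   [assign_peaks_to_stimuli()].
#' @return object of class \code{tuning_result}: list with \code{response}
#'   (3-d array roi x frequency x attenuation), \code{tf}, \code{responsive},
#'   \code{saturated}, \code{frequencies}, \code{attenuations}.
#' @export
build_tuning <- function(assigned, trials, roi_ids, n_frames,
                         k_sd = 3, n_shifts = 20, saturated = NULL,
                         window = 0.2, frame_rate = NULL) {
  frame_rate <- frame_rate %||% attr(trials, "frame_rate") %||% 10
  freqs <- attr(trials, "frequencies") %||% sort(unique(trials$frequency))
  attns <- attr(trials, "attenuations") %||% sort(unique(trials$attenuation))
  n_rep <- attr(trials, "n_repeats") %||%
    (nrow(trials) / (length(freqs) * length(attns)))
  if (nrow(assigned)) {
    assert_that(all(assigned$frequency %in% freqs) &&
                  all(assigned$attenuation %in% attns),
                "assigned events reference combinations outside the trial grid")
  }
  n_roi <- length(roi_ids)
  saturated <- saturated %||% rep(FALSE, n_roi)

  combo_means <- function(ev) {
    m <- matrix(0, length(freqs), length(attns),
                dimnames = list(freqs, attns))
    if (nrow(ev)) {
      agg <- stats::aggregate(amplitude ~ frequency + attenuation, ev, sum)
      m[cbind(match(agg$frequency, freqs), match(agg$attenuation, attns))] <-
        agg$amplitude / n_rep
    }
    m
  }

  resp_arr <- array(0, dim = c(n_roi, length(freqs), length(attns)),
                    dimnames = list(roi_ids, freqs, attns))
  tf <- rep(NA_real_, n_roi)
  responsive <- rep(FALSE, n_roi)
  offsets <- floor(n_frames * seq_len(n_shifts) / (n_shifts + 1))

  for (r in seq_len(n_roi)) {
    ev <- assigned[assigned$roi == roi_ids[r], , drop = FALSE]
    obs <- combo_means(ev)
    resp_arr[r, , ] <- obs
    if (saturated[r] || !nrow(ev)) next
    # null: circularly shift this ROI's event frames, reassign, tabulate
    null_vals <- unlist(lapply(offsets, function(off) {
      sh <- ev
      sh$frame <- ((ev$frame - 1L + off) %% n_frames) + 1L
      re <- assign_peaks_to_stimuli(sh[c("roi", "frame", "amplitude")], trials,
                                    window = window, frame_rate = frame_rate)
      combo_means(re$assigned)
    }))
    thr <- mean(null_vals) + k_sd * stats::sd(null_vals)
    if (!is.finite(thr)) thr <- Inf
    responsive[r] <- any(obs > thr)
    if (responsive[r]) {
      prof <- rowMeans(obs)
      tf[r] <- freqs[which.max(prof)]  # which.max ties -> first = lower freq
    }
  }

  structure(list(response = resp_arr, tf = tf, responsive = responsive,
                 saturated = saturated, roi_ids = roi_ids,
                 frequencies = freqs, attenuations = attns),
            class = "tuning_result")
}

#' Full imaging pipeline: raw traces to tuning result
#'
#' dF/F, kinetics-screened peak detection, 200-ms stimulus assignment,
#' saturation screening, and tuning construction.
#'
#' @param traces a \code{roi_trace_set}.
#' @param trials a [make_trial_table()] trial table.
#' @param threshold,rise_max,decay_range peak-detection parameters.
#' @param window assignment window (s).
#' @param k_sd,n_shifts responsiveness-null parameters.
#' @param baseline_percentile dF/F baseline percentile.
#' @return a \code{tuning_result}, with the intermediate \code{events},
#'   \code{assigned} and \code{excluded} tables attached as attributes.
#' @export
run_tuning_pipeline <- function(traces, trials, threshold = 10,
                                rise_max = 0.3, decay_range = c(0.1, 2),
                                window = 0.2, k_sd = 3, n_shifts = 20,
                                baseline_percentile = 20) {
  dff <- compute_dff(traces, baseline_percentile = baseline_percentile)
  events <- detect_peaks(dff, frame_rate = traces$frame_rate,
                         threshold = threshold, rise_max = rise_max,
                         decay_range = decay_range)
  asg <- assign_peaks_to_stimuli(events, trials, window = window,
                                 frame_rate = traces$frame_rate)
  sat <- flag_saturated(traces)
  tun <- build_tuning(asg$assigned, trials, roi_ids = traces$roi_ids,
                      n_frames = ncol(traces$fluorescence), k_sd = k_sd,
                      n_shifts = n_shifts, saturated = sat, window = window,
                      frame_rate = traces$frame_rate)
  attr(tun, "events") <- events
  attr(tun, "assigned") <- asg$assigned
  attr(tun, "excluded") <- asg$excluded
  tun
}
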