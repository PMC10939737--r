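#' Write / read a voltammetry session (CSV matrix + JSON header)
#'
#' The current matrix goes to \code{<stem>.csv} (scans as rows, no header);
#' waveform parameters and the stimulus schedule go to \code{<stem>.json}.
#'
#' @param session a \code{voltammetry_session}.
#' @param stem file path without extension.
#' @return the stem, invisibly.
#' @export
write_voltammetry_session <- function(session, stem) {
  stopifnot(inherits(session, "voltammetry_session"))
  utils::write.table(session$currents, paste0(stem, ".csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  hdr <- list(
    waveform = session$waveform[c("v_min", "v_max", "scan_rate", "sample_hz")],
    scan_period = session$scan_period,
    n_scans = nrow(session$currents),
    n_samples = ncol(session$currents),
    stimuli = session$stimuli)
  jsonlite::write_json(hdr, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' @rdname write_voltammetry_session
#' @export
read_voltammetry_session <- function(stem) {
  hdr <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  cur <- as.matrix(utils::read.table(paste0(stem, ".csv"), sep = ","))
  dimnames(cur) <- NULL
  wf <- scan_waveform(v_min = hdr$waveform$v_min, v_max = hdr$waveform$v_max,
                      scan_rate = hdr$waveform$scan_rate,
                      scan_period = hdr$scan_period,
                      sample_hz = hdr$waveform$sample_hz)
  structure(list(
    currents = cur, waveform = wf, scan_period = hdr$scan_period,
    time = (seq_len(nrow(cur)) - 1) * hdr$scan_period,
    stimuli = as.data.frame(hdr$stimuli)), class = "voltammetry_session")
}

#' Write / read ROI traces in long CSV (time, roi, value)
#'
#' @param traces a \code{roi_trace_set}.
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
write_roi_traces <- function(traces, path) {
  stopifnot(inherits(traces, "roi_trace_set"))
  n_frames <- ncol(traces$fluorescence)
  long <- data.frame(
    time = rep((seq_len(n_frames) - 1L) / traces$frame_rate,
               each = length(traces$roi_ids)),
    roi = rep(traces$roi_ids, n_frames),
    value = as.vector(traces$fluorescence))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_roi_traces
#' @param frame_rate frames per second of the stored traces.
#' @export
read_roi_traces <- function(path, frame_rate = 10) {
  long <- utils::read.csv(path)
  rois <- sort(unique(long$roi))
  times <- sort(unique(long$time))
  fmat <- matrix(NA_real_, length(rois), length(times))
  fmat[cbind(match(long$roi, rois), match(long$time, times))] <- long$value
  structure(list(fluorescence = fmat, frame_rate = frame_rate,
                 roi_ids = rois), class = "roi_trace_set")
}

#' Write / read a trial table as CSV
#' @param trials a [make_trial_table()] table.
#' @param path CSV path.
#' @export
write_trial_table <- function(trials, path) {
  meta <- list(frequencies = attr(trials, "frequencies"),
               attenuations = attr(trials, "attenuations"),
               n_repeats = attr(trials, "n_repeats"),
               frame_rate = attr(trials, "frame_rate"))
  utils::write.csv(as.data.frame(trials), path, row.names = FALSE)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  df <- utils::read.csv(path)
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list(frequencies = sort(unique(df$frequency)),
         attenuations = sort(unique(df$attenuation)),
         n_repeats = nrow(df) /
           (length(unique(df$frequency)) * length(unique(df$attenuation))),
         frame_rate = 10)
  }
  structure(df, frequencies = meta$frequencies,
            attenuations = meta$attenuations, n_repeats = meta$n_repeats,
            frame_rate = meta$frame_rate,
            class = c("trial_table", "data.frame"))
}

#' Write / read a startle session as CSV (one row per trial)
#' @param session a \code{ppi_session}.
#' @param path CSV path.
#' @export
write_ppi_session <- function(session, path) {
  stopifnot(inherits(session, "ppi_session"))
  df <- session$trials
  df$background_freq <- session$background_freq
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ppi_session
#' @export
read_ppi_session <- function(path) {
  df <- utils::read.csv(path)
  bg <- if ("background_freq" %in% names(df)) df$background_freq[1] else 16.4
  df$background_freq <- NULL
  structure(list(trials = df, background_freq = bg), class = "ppi_session")
}

#' Write a ground-truth record as a JSON sidecar
#' @param truth a generator ground-truth object.
#' @param path JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  strip <- unclass(truth)
  strip$params <- lapply(unclass(strip$params %||% list()), unclass)
  jsonlite::write_json(strip, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
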