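# Independent brute-force oracles used to cross-check the package's
# implementations. Deliberately written in the most literal way possible.

# per-stimulus background subtraction by explicit loops
oracle_bg_subtract <- function(session, n_background = 10, post_window = 10) {
  cur <- session$currents
  period <- session$scan_period
  for (i in seq_len(nrow(session$stimuli))) {
    onset <- session$stimuli$onset[i]
    onset_scan <- floor(onset / period + 1e-9) + 1L
    first <- onset_scan - n_background
    last <- min(nrow(cur),
                floor((onset + session$stimuli$duration[i] + post_window) /
                        period + 1e-9) + 2L)
    bg <- rep(0, ncol(cur))
    for (s in first:(onset_scan - 1L)) bg <- bg + session$currents[s, ]
    bg <- bg / n_background
    for (s in first:last) cur[s, ] <- session$currents[s, ] - bg
  }
  cur
}

# elementwise dF/F with a given percentile baseline
oracle_dff <- function(fmat, pct = 20) {
  out <- fmat
  for (r in seq_len(nrow(fmat))) {
    f0 <- stats::quantile(fmat[r, ], pct / 100, names = FALSE)
    for (j in seq_len(ncol(fmat))) out[r, j] <- (fmat[r, j] - f0) / f0 * 100
  }
  out
}

# transition-percentage tabulation by explicit counting
oracle_heatmap <- function(before, after, grid) {
  m <- matrix(0, length(grid), length(grid), dimnames = list(grid, grid))
  for (i in seq_along(grid)) {
    sel <- before == grid[i]
    if (!any(sel)) next
    for (j in seq_along(grid)) {
      m[i, j] <- 100 * sum(sel & after == grid[j]) / sum(sel)
    }
  }
  m
}

# two-sample KS D as an explicit sup over all pooled thresholds
oracle_ks_d <- function(x, y) {
  d <- 0
  for (t in c(x, y)) {
    d <- max(d, abs(mean(x <= t) - mean(y <= t)))
  }
  d
}

# exact two-sided signed-rank p by enumerating all sign assignments
oracle_signed_rank <- function(x) {
  x <- x[x != 0]
  n <- length(x)
  r <- rank(abs(x))
  v_obs <- sum(r[x > 0])
  vs <- vapply(seq_len(2^n) - 1L, function(mask) {
    signs <- bitwAnd(bitwShiftR(mask, seq_len(n) - 1L), 1L) == 1L
    sum(r[signs])
  }, numeric(1))
  mu <- n * (n + 1) / 4
  p <- mean(abs(vs - mu) >= abs(v_obs - mu) - 1e-12)
  list(statistic = v_obs, p = min(1, p))
}

# closed-form simple least squares via the normal equations
oracle_lsq <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  yhat <- intercept + slope * x
  ss_res <- sum((y - yhat)^2); ss_tot <- sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept,
       r2 = if (ss_tot == 0) 0 else 1 - ss_res / ss_tot)
}

# PPI arithmetic computed trial by trial
oracle_ppi <- function(session) {
  tr <- session$trials
  ref <- mean(tr$magnitude[tr$block == 3 & tr$type == "startle_only"])
  pp <- tr[tr$type == "prepulse", ]
  deltas <- sort(unique(pp$prepulse_delta))
  vapply(deltas, function(d) {
    mean((1 - pp$magnitude[pp$prepulse_delta == d] / ref) * 100)
  }, numeric(1))
}

# minimal hand-built voltammetry session for oracle tests
make_tiny_session <- function(seed, n_scans = 240, n_stim = 2) {
  wf <- scan_waveform()
  onsets <- 3 + (seq_len(n_stim) - 1) * 12
  withr::with_seed(seed, {
    structure(list(
      currents = matrix(rnorm(n_scans * wf$n_samples), nrow = n_scans),
      waveform = wf, scan_period = 0.1,
      time = (seq_len(n_scans) - 1) * 0.1,
      stimuli = data.frame(onset = onsets, duration = 0.5, attenuation = 0,
                           epoch = "baseline")), class = "voltammetry_session")
  })
}
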