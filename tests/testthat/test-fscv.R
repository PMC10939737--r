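test_that("background subtraction zeroes a constant background and preserves an added kernel", {
  wf <- scan_waveform()
  n_scans <- 300
  bg <- sin(seq_len(wf$n_samples) / 10) + 2
  cur <- matrix(rep(bg, each = n_scans), nrow = n_scans)
  stim <- data.frame(onset = 10, duration = 1, attenuation = 0,
                     epoch = "baseline")
  ses <- structure(list(currents = cur, waveform = wf, scan_period = 0.1,
                        time = (seq_len(n_scans) - 1) * 0.1, stimuli = stim),
                   class = "voltammetry_session")
  sub <- background_subtract(ses)
  win <- sub$windows$first[1]:sub$windows$last[1]   # only windows are subtracted
  expect_lt(max(abs(sub$currents[win, ])), 1e-12)

  # linearity: an additive kernel at the oxidation sample survives unchanged
  j <- attr(extract_oxidation_trace(ses), "sample")
  kern <- 0.8 * gamma_pulse(ses$time - 10.4, 4, 2)
  ses2 <- ses
  ses2$currents[, j] <- ses2$currents[, j] + kern
  sub2 <- background_subtract(ses2)
  expect_lt(max(abs(extract_oxidation_trace(sub2)$current[win] - kern[win])),
            1e-9)
})

test_that("background subtraction is idempotent on stable backgrounds", {
  ses <- make_tiny_session(seed = 5)
  ses$currents <- ses$currents * 0 + 3   # stable background, no noise
  sub1 <- background_subtract(ses, n_background = 5, post_window = 2)
  sub2 <- background_subtract(sub1, n_background = 5, post_window = 2)
  expect_equal(sub1$currents, sub2$currents)
})

test_that("background subtraction fails loudly without enough pre-stimulus scans", {
  ses <- make_tiny_session(seed = 1)
  ses$stimuli$onset[1] <- 0.3   # only 3 scans precede
  expect_error(background_subtract(ses, n_background = 10), "stimulus 1",
               class = "acxplast_window_error")
})

test_that("oxidation-channel extraction maps 1.4 V to a unique ascending sample", {
  wf <- scan_waveform()
  up <- which(wf$ascending)
  hits <- up[abs(wf$voltage[up] - 1.4) == min(abs(wf$voltage[up] - 1.4))]
  expect_length(hits, 1L)
  expect_equal(wf$voltage[hits], 1.4)

  ses <- make_tiny_session(seed = 2)
  ses$currents[] <- 0
  expect_equal(extract_oxidation_trace(ses)$current, rep(0, nrow(ses$currents)))
  expect_error(extract_oxidation_trace(ses, oxidation_voltage = 2),
               class = "acxplast_range_error")
})

test_that("calibration fitting matches closed-form least squares", {
  conc <- c(0.1, 0.5, 1, 2, 5)
  cal <- fit_calibration(rep(conc, each = 3), rep(2 * conc, each = 3))
  expect_equal(cal$slope, 2, tolerance = 1e-12)
  expect_equal(cal$intercept, 0, tolerance = 1e-12)
  expect_equal(cal$r2, 1, tolerance = 1e-12)

  flat <- fit_calibration(conc, rep(3, 5))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_false(flat$usable)
  expect_error(fit_calibration(rep(1, 4), 1:4),
               class = "acxplast_singular_fit")

  withr::with_seed(7, {
    for (i in 1:20) {
      y <- 1.5 * conc + 0.3 + rnorm(5, 0, 0.2)
      cal <- fit_calibration(conc, y)
      o <- oracle_lsq(conc, y)
      expect_equal(cal$slope, o$slope, tolerance = 1e-9)
      expect_equal(cal$intercept, o$intercept, tolerance = 1e-9)
      expect_equal(cal$r2, o$r2, tolerance = 1e-9)
    }
  })
})

test_that("current-to-concentration inverts the calibration line", {
  cal <- fit_calibration(c(0.1, 0.5, 1, 2, 5), 2 * c(0.1, 0.5, 1, 2, 5) + 1)
  expect_equal(current_to_concentration(2 * 1 + 1, cal), 1, tolerance = 1e-9)
  withr::with_seed(3, {
    x <- rnorm(50)
    expect_equal(current_to_concentration(x, cal), (x - cal$intercept) / cal$slope)
  })
  flat <- fit_calibration(c(1, 2), c(5, 5))
  expect_error(current_to_concentration(1, flat),
               class = "acxplast_singular_fit")
})

test_that("transient metrics recover a linear ramp's 10-90% kinetics", {
  tt <- seq(0, 20, by = 0.01)
  y <- pmax(0, pmin(tt - 5, 1, 7 - tt))  # ramp up 5..6, plateau, down 6..7
  m <- transient_metrics(data.frame(time = tt, v = y), stimulus_onset = 4.5,
                         duration = 0.1, post_window = 5)
  expect_equal(m$rise_time, 0.8, tolerance = 1e-6)
  expect_equal(m$decay_time, 0.8, tolerance = 1e-6)
  expect_equal(m$peak_amp, 1, tolerance = 1e-9)

  expect_null(transient_metrics(data.frame(time = tt, v = rep(0, length(tt))),
                                stimulus_onset = 4.5, duration = 0.1,
                                post_window = 5))
  expect_error(transient_metrics(data.frame(time = tt, v = y),
                                 stimulus_onset = 15, duration = 5),
               class = "acxplast_window_error")
})

test_that("transient metrics are offset-invariant and amplitude-equivariant", {
  tt <- seq(0, 30, by = 0.1)
  y <- 2 * gamma_pulse(tt - 5.3, 4.6, 2.1) + rnorm(length(tt), 0, 0.01)
  m0 <- transient_metrics(data.frame(time = tt, v = y), 5, duration = 0.1)
  m_off <- transient_metrics(data.frame(time = tt, v = y + 7), 5, duration = 0.1)
  m_scl <- transient_metrics(data.frame(time = tt, v = 3 * y), 5, duration = 0.1)
  expect_equal(m_off$latency, m0$latency, tolerance = 1e-9)
  expect_equal(m_off$rise_time, m0$rise_time, tolerance = 1e-9)
  expect_equal(m_off$decay_time, m0$decay_time, tolerance = 1e-9)
  expect_equal(m_off$peak_amp, m0$peak_amp, tolerance = 1e-9)
  expect_equal(m_scl$peak_amp, 3 * m0$peak_amp, tolerance = 1e-9)
  expect_equal(m_scl$rise_time, m0$rise_time, tolerance = 1e-9)
})

test_that("pairing reduction normalizes to baseline and handles the trivial cases", {
  pk <- data.frame(peak = c(rep(10, 5), rep(5, 5)),
                   epoch = rep(c("baseline", "pairing"), each = 5))
  r <- pairing_reduction(pk)
  expect_equal(r$reduction_pct, 50)
  expect_equal(unname(r$epoch_mean["baseline"]), 100)

  same <- data.frame(peak = rep(8, 12),
                     epoch = rep(c("baseline", "pairing"), each = 6),
                     recording = rep(1:3, 4))
  r2 <- pairing_reduction(same)
  expect_equal(r2$reduction_pct, 0)
  expect_gt(r2$test$p, 0.9)

  bad <- data.frame(peak = c(0, 0, 0, 1), epoch = c(rep("baseline", 3), "pairing"))
  expect_error(pairing_reduction(bad), class = "acxplast_normalization_error")
})

test_that("modality correlation reports r2, slope and p", {
  x <- c(1, 2, 3, 4)
  r <- correlate_modalities(x, 3 * x)
  expect_equal(r$r2, 1, tolerance = 1e-12)
  expect_equal(r$slope, 3, tolerance = 1e-12)

  withr::with_seed(11, {
    xn <- rnorm(200); yn <- rnorm(200)
    expect_lt(correlate_modalities(xn, yn)$r2, 0.05)
  })
  withr::with_seed(12, {
    x4 <- c(1, 2, 4, 8); y4 <- 2 * x4 + rnorm(4, 0, 0.1)
    expect_gte(correlate_modalities(x4, y4)$r2, 0.95)
  })
  expect_error(correlate_modalities(1:2, 1:2), "3 paired")
})
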