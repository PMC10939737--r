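test_that("dF/F handles constant, doubling and invalid-baseline traces", {
  m <- matrix(5, 2, 100)
  d <- compute_dff(m)
  expect_equal(unname(d[1, ]), rep(0, 100))

  m2 <- matrix(10, 1, 100)
  m2[1, 50] <- 20
  d2 <- compute_dff(m2)
  expect_equal(d2[1, 50], 100)

  m3 <- matrix(c(rep(0, 100), rep(10, 100)), 2, 100, byrow = TRUE)
  d3 <- compute_dff(m3)
  expect_true(all(is.na(d3[1, ])))
  expect_true(attr(d3, "invalid")[1])
})

test_that("dF/F equals the elementwise oracle and is scale-invariant", {
  withr::with_seed(31, {
    for (i in 1:5) {
      m <- matrix(rlnorm(20 * 200, 3, 0.2), 20, 200)
      expect_equal(unname(compute_dff(m)), unname(oracle_dff(m)),
                   tolerance = 1e-12, ignore_attr = TRUE)
      expect_equal(compute_dff(7.3 * m), compute_dff(m), tolerance = 1e-9,
                   ignore_attr = TRUE)
    }
  })
})

test_that("a single clean transient yields one event at the true peak", {
  fps <- 10
  y <- numeric(300)
  kern <- transient_kernel(seq_len(20) / fps, 0.02, 0.35)
  y[101 + seq_along(kern)] <- 30 * kern
  ev <- detect_peaks(y, frame_rate = fps, threshold = 10)
  expect_equal(nrow(ev), 1L)
  expect_lte(abs(ev$frame - (101 + which.max(kern))), 1)

  expect_equal(nrow(detect_peaks(rnorm(300, 0, 1), frame_rate = fps,
                                 threshold = 10)), 0L)
  expect_error(detect_peaks(y[1:5], frame_rate = fps, threshold = 10),
               "shorter")
})

test_that("peak detection keeps recall and precision high at SNR 5", {
  fps <- 10
  withr::with_seed(32, {
    n_frames <- 5000
    true_frames <- sort(sample(seq(50, n_frames - 50, by = 40), 50))
    kern <- transient_kernel(seq_len(20) / fps, 0.02, 0.35)
    y <- rnorm(n_frames, 0, 2)     # amplitude 10 on sd 2 -> SNR 5
    for (f in true_frames) {
      idx <- f + seq_along(kern)
      y[idx] <- y[idx] + 10 * kern
    }
    ev <- detect_peaks(y, frame_rate = fps, threshold = 6)
    true_peaks <- true_frames + which.max(kern)
    matched <- vapply(true_peaks, function(tp) any(abs(ev$frame - tp) <= 2),
                      logical(1))
    recall <- mean(matched)
    precision <- mean(vapply(ev$frame, function(f)
      any(abs(true_peaks - f) <= 2), logical(1)))
    expect_gte(recall, 0.95)
    expect_gte(precision, 0.95)
  })
})

test_that("the 200-ms assignment rule includes 150-ms and excludes 250-ms events", {
  tr <- structure(data.frame(frequency = 9.8, attenuation = 0,
                             onset_frame = 100L),
                  frequencies = 9.8, attenuations = 0, n_repeats = 1,
                  frame_rate = 10, class = c("trial_table", "data.frame"))
  mk_ev <- function(frame) data.frame(roi = 1L, frame = frame, amplitude = 20,
                                      rise_time = 0.1, decay_time = 0.5,
                                      rise_ok = TRUE, decay_ok = TRUE)
  # frame index is 1-based: frame 101.5 does not exist, use 101 (100 ms) and
  # 102 (200 ms, inclusive) vs 103 (300 ms)
  a1 <- assign_peaks_to_stimuli(mk_ev(102L), tr)
  expect_equal(nrow(a1$assigned), 1L)
  expect_equal(a1$assigned$trial, 1L)
  a2 <- assign_peaks_to_stimuli(mk_ev(103L), tr)
  expect_equal(nrow(a2$assigned), 0L)
  expect_equal(a2$excluded$reason, "outside 200-ms window")

  empty <- assign_peaks_to_stimuli(mk_ev(102L), tr[0, , drop = FALSE])
  expect_equal(nrow(empty$assigned), 0L)
  expect_equal(nrow(empty$excluded), 1L)
})

test_that("every detected event is assigned exactly once or logged excluded", {
  trials <- make_trial_table(n_repeats = 6, seed = 41)
  p <- neuron_gen_params(n_neurons = 40)
  g <- generate_roi_traces(p, trials, seed = 41)
  dff <- compute_dff(g$traces)
  ev <- detect_peaks(dff, frame_rate = 10)
  asg <- assign_peaks_to_stimuli(ev, trials)
  expect_equal(nrow(asg$assigned) + nrow(asg$excluded), nrow(ev))
  key <- function(d) paste(d$roi, d$frame)
  expect_length(intersect(key(asg$assigned), key(asg$excluded)), 0)
})

test_that("assignment rejects schedules with overlapping windows", {
  tr <- structure(data.frame(frequency = c(9.8, 9.8), attenuation = 0,
                             onset_frame = c(100L, 101L)),
                  frame_rate = 10, class = c("trial_table", "data.frame"))
  ev <- data.frame(roi = 1L, frame = 102L, amplitude = 20, rise_time = 0.1,
                   decay_time = 0.5, rise_ok = TRUE, decay_ok = TRUE)
  expect_error(assign_peaks_to_stimuli(ev, tr),
               class = "acxplast_schedule_error")
})

test_that("TF ties break to the lower frequency", {
  tr <- make_trial_table(frequencies = c(9.8, 19.6), attenuations = 0,
                         n_repeats = 4, seed = 2)
  i98 <- which(tr$frequency == 9.8)[1]
  i196 <- which(tr$frequency == 19.6)[1]
  # one identical-amplitude assigned event per frequency: an exact tie
  both <- data.frame(roi = 1L, frame = tr$onset_frame[c(i98, i196)] + 1L,
                     amplitude = 25, rise_time = 0.1, decay_time = 0.5,
                     rise_ok = TRUE, decay_ok = TRUE,
                     trial = c(i98, i196), frequency = c(9.8, 19.6),
                     attenuation = 0)
  tun <- build_tuning(both, tr, roi_ids = 1L,
                      n_frames = max(tr$onset_frame) + 100L,
                      k_sd = 0, n_shifts = 5)
  expect_true(tun$responsive[1])
  expect_equal(tun$tf[1], 9.8)
})

test_that("clipped traces are flagged saturated, healthy ones are not", {
  healthy <- matrix(rnorm(2000, 100, 2), 1)
  healthy[1, 500:520] <- 100 + 50 * transient_kernel(seq_len(21) / 10, 0.02, 0.35)
  clipped <- pmin(matrix(rnorm(2000, 100, 2), 1) + 60, 120)
  expect_false(flag_saturated(healthy))
  expect_true(flag_saturated(clipped))
})
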