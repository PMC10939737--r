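test_that("PPI arithmetic covers the fixed points of the formula", {
  mk <- function(mags) {
    trials <- rbind(
      data.frame(block = 2L, type = "startle_only", prepulse_delta = NA,
                 magnitude = 1),
      data.frame(block = 3L, type = "startle_only", prepulse_delta = NA,
                 magnitude = rep(1, 5)),
      data.frame(block = 3L, type = "prepulse", prepulse_delta = c(4, 8, 16),
                 magnitude = mags),
      data.frame(block = 4L, type = "startle_only", prepulse_delta = NA,
                 magnitude = 1))
    structure(list(trials = trials, background_freq = 16.4),
              class = "ppi_session")
  }
  tab <- compute_ppi(mk(c(1, 0, 0.5)))
  expect_equal(tab$ppi_mean[tab$prepulse_delta == 4], 0)
  expect_equal(tab$ppi_mean[tab$prepulse_delta == 8], 100)
  expect_equal(tab$ppi_mean[tab$prepulse_delta == 16], 50)

  # invariance under rescaling all magnitudes
  s1 <- mk(c(0.9, 0.4, 0.2)); s2 <- mk(c(0.9, 0.4, 0.2))
  s2$trials$magnitude <- 13 * s2$trials$magnitude
  expect_equal(compute_ppi(s1)$ppi_mean, compute_ppi(s2)$ppi_mean,
               tolerance = 1e-12)
})

test_that("PPI means match the trial-level oracle on generated sessions", {
  withr::with_seed(61, {
    for (i in 1:10) {
      g <- generate_ppi_session(ppi_gen_params(), seed = sample.int(1e6, 1))
      expect_equal(compute_ppi(g$session)$ppi_mean, oracle_ppi(g$session),
                   tolerance = 1e-12)
    }
  })
})

test_that("session generator builds the four-block structure deterministically", {
  p <- ppi_gen_params()
  g1 <- generate_ppi_session(p, seed = 7)
  g2 <- generate_ppi_session(p, seed = 7)
  expect_identical(g1$session$trials, g2$session$trials)
  tr <- g1$session$trials
  expect_setequal(unique(tr$block), c(2L, 3L, 4L))
  expect_equal(sum(tr$block == 3 & tr$type == "prepulse"), 7 * 10)
  expect_equal(sum(tr$block == 3 & tr$type == "startle_only"), 10)
  expect_true(all(tr$magnitude >= 0))
})

test_that("noiseless logistic sessions give back the exact threshold", {
  g <- generate_ppi_session(ppi_gen_params(true_fdt = 8, startle_cv = 0),
                            seed = 1)
  r <- analyze_ppi_session(g$session)
  expect_false(r$excluded)
  expect_equal(r$fdt, 8, tolerance = 1e-3)
  expect_equal(r$r2, 1, tolerance = 1e-9)

  g4 <- generate_ppi_session(ppi_gen_params(true_fdt = 4, startle_cv = 0),
                             seed = 2)
  expect_equal(analyze_ppi_session(g4$session)$fdt, 4, tolerance = 1e-3)
})

test_that("flat-PPI sessions are excluded by the r2 rule", {
  g <- generate_ppi_session(ppi_gen_params(max_ppi = 0), seed = 3)
  r <- analyze_ppi_session(g$session)
  expect_true(r$excluded)
  expect_true(is.na(r$fdt))
})

test_that("ASR pools startle-only blocks and measures habituation", {
  trials <- rbind(
    data.frame(block = 2L, type = "startle_only", prepulse_delta = NA,
               magnitude = rep(2, 5)),
    data.frame(block = 3L, type = "startle_only", prepulse_delta = NA,
               magnitude = rep(2, 5)),
    data.frame(block = 4L, type = "startle_only", prepulse_delta = NA,
               magnitude = rep(1, 5)))
  ses <- structure(list(trials = trials, background_freq = 16.4),
                   class = "ppi_session")
  r <- compute_asr(ses)
  expect_equal(r$asr, mean(c(2, 2, 1)))
  expect_equal(r$habituation_ratio, 0.5)
  expect_equal(compute_asr(ses, blocks = 3)$asr, 2)
  withr::with_seed(62, {
    g <- generate_ppi_session(ppi_gen_params(), seed = 4)
    tr <- g$session$trials
    expect_equal(compute_asr(g$session)$asr,
                 mean(tr$magnitude[tr$type == "startle_only"]),
                 tolerance = 1e-12)
  })
})

test_that("condition comparison reports percent change and paired stats", {
  mk_fit <- function(fdt, asr) {
    structure(list(fdt = fdt, asr = asr, r2 = 0.95, excluded = FALSE),
              class = "fdt_result")
  }
  pre <- lapply(c(8, 9, 7.5, 8.5), mk_fit, asr = 1)
  expect_warning(same <- compare_conditions(pre, pre), NA)
  expect_equal(same$fdt_change_pct, 0)
  expect_equal(same$fdt_test$p, 1)

  post <- lapply(c(8, 9, 7.5, 8.5) * 0.4, mk_fit, asr = 1)
  down <- compare_conditions(pre, post)
  expect_equal(down$fdt_change_pct, -60, tolerance = 1e-9)

  excl <- structure(list(fdt = NA, asr = 1, r2 = 0.2, excluded = TRUE),
                    class = "fdt_result")
  expect_error(compare_conditions(list(pre[[1]], excl, excl, excl),
                                  list(pre[[1]], excl, excl, excl)),
               class = "acxplast_insufficient_data")
})
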