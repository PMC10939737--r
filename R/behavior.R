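#' Parameters for the startle / prepulse-inhibition session simulator
#'
#' Defaults mirror a standard frequency-discrimination PPI session: a
#' 16.4-kHz background, prepulses 0/1/2/4/8/16/32\% below background, 10
#' repeats per prepulse interleaved with 10 startle-only trials in block 3,
#' and startle-only blocks 2 and 4 around it. Startle forces are positive
#' and right-skewed, hence multiplicative lognormal noise.
#'
#' @param true_fdt ground-truth frequency-discrimination threshold (\% below
#'   background); must lie within the prepulse grid span.
#' @param max_ppi asymptotic PPI (\%), in (0, 100].
#' @param logistic_slope slope of the psychometric logistic in log-Delta-f.
#' @param startle_mean mean startle-only magnitude (force units).
#' @param startle_cv coefficient of variation of startle magnitudes.
#' @param n_repeats_per_prepulse repeats of each prepulse in block 3.
#' @param prepulse_grid prepulse frequency decrements (\%), including 0.
#' @param n_startle_block2,n_startle_block3,n_startle_block4 startle-only
#'   trial counts per block.
#' @param background_freq background tone (kHz).
#' @return object of class \code{ppi_gen_params}.
#' @export
ppi_gen_params <- function(true_fdt = 8, max_ppi = 60, logistic_slope = 2,
                           startle_mean = 1, startle_cv = 0.15,
                           n_repeats_per_prepulse = 10,
                           prepulse_grid = c(0, 1, 2, 4, 8, 16, 32),
                           n_startle_block2 = 10, n_startle_block3 = 10,
                           n_startle_block4 = 10, background_freq = 16.4) {
  assert_that(length(prepulse_grid) >= 1, "prepulse grid must be nonempty")
  assert_that(startle_mean > 0, "startle_mean must be positive")
  assert_that(max_ppi >= 0 && max_ppi <= 100, "max_ppi must lie in [0, 100]")
  pos <- prepulse_grid[prepulse_grid > 0]
  assert_that(true_fdt >= min(pos) && true_fdt <= max(pos),
              "true_fdt must lie within the prepulse grid span")
  assert_that(n_repeats_per_prepulse >= 1, "need at least one repeat per prepulse")
  structure(list(
    true_fdt = true_fdt, max_ppi = max_ppi, logistic_slope = logistic_slope,
    startle_mean = startle_mean, startle_cv = startle_cv,
    n_repeats_per_prepulse = n_repeats_per_prepulse,
    prepulse_grid = prepulse_grid,
    n_startle_block2 = n_startle_block2,
    n_startle_block3 = n_startle_block3,
    n_startle_block4 = n_startle_block4,
    background_freq = background_freq), class = "ppi_gen_params")
}

# psychometric inhibition fraction in [0, 1]: logistic in log Delta-f,
# anchored to 0 at Delta-f = 0
ppi_logistic <- function(delta_f, fdt, slope) {
  out <- numeric(length(delta_f))
  out[is.na(delta_f)] <- NA_real_
  pos <- !is.na(delta_f) & delta_f > 0
  out[pos] <- 1 / (1 + exp(-slope * (log(delta_f[pos]) - log(fdt))))
  out
}

#' Simulate a four-block startle / PPI session
#'
#' Block 1 is acclimation (no trials); block 2 startle-only; block 3 mixes
#' \code{n_repeats_per_prepulse} repeats of every prepulse with startle-only
#' trials in a seeded pseudo-random (Fisher-Yates) order; block 4 is
#' startle-only again. Prepulse-trial magnitudes are
#' \code{startle_mean * (1 - logistic(Delta-f) * max_ppi/100)} under
#' multiplicative lognormal noise with unit mean.
#'
#' @param params a [ppi_gen_params()] object.
#' @param seed integer seed.
#' @return list(session, truth): a \code{ppi_session} (trials data.frame:
#'   block, type, prepulse_delta, magnitude; background_freq attribute) and
#'   the ground truth (true FDT, max PPI, slope, per-trial expected
#'   inhibition).
#' @export
generate_ppi_session <- function(params, seed = 1L) {
  stopifnot(inherits(params, "ppi_gen_params"))
  sdlog <- sqrt(log(1 + params$startle_cv^2))
  mlog <- -sdlog^2 / 2  # unit-mean lognormal
  with_seed(seed, {
    b3_pp <- rep(params$prepulse_grid, each = params$n_repeats_per_prepulse)
    b3 <- data.frame(block = 3L,
                     type = c(rep("prepulse", length(b3_pp)),
                              rep("startle_only", params$n_startle_block3)),
                     prepulse_delta = c(b3_pp, rep(NA_real_,
                                                   params$n_startle_block3)))
    b3 <- b3[sample.int(nrow(b3)), ]
    trials <- rbind(
      data.frame(block = 2L, type = "startle_only",
                 prepulse_delta = rep(NA_real_, params$n_startle_block2)),
      b3,
      data.frame(block = 4L, type = "startle_only",
                 prepulse_delta = rep(NA_real_, params$n_startle_block4)))
    inhib <- numeric(nrow(trials))
    pp <- trials$type == "prepulse"
    inhib[pp] <- ppi_logistic(trials$prepulse_delta[pp], params$true_fdt,
                              params$logistic_slope) * params$max_ppi / 100
    noise <- if (params$startle_cv > 0) {
      stats::rlnorm(nrow(trials), mlog, sdlog)
    } else rep(1, nrow(trials))
    trials$magnitude <- params$startle_mean * (1 - inhib) * noise
    rownames(trials) <- NULL
    session <- structure(list(trials = trials,
                              background_freq = params$background_freq),
                         class = "ppi_session")
    truth <- structure(list(true_fdt = params$true_fdt,
                            max_ppi = params$max_ppi,
                            logistic_slope = params$logistic_slope,
                            expected_inhibition = inhib,
                            params = params, seed = seed),
                       class = "ppi_ground_truth")
    list(session = session, truth = truth)
  })
}

#' Compute prepulse inhibition per prepulse frequency difference
#'
#' \code{PPI = (1 - prepulse-trial startle / startle-only startle) * 100},
#' with the startle-only reference taken as the mean magnitude of the
#' interleaved block-3 startle-only trials. Negative values (facilitation)
#' are retained.
#'
#' @param session a \code{ppi_session}.
#' @param reference_block block whose startle-only trials define the
#'   reference (3; the interleaved controls).
#' @return data.frame: prepulse_delta (\%), ppi_mean, ppi_sem, n, plus the
#'   \code{reference} magnitude as an attribute.
#' @export
compute_ppi <- function(session, reference_block = 3L) {
  stopifnot(inherits(session, "ppi_session"))
  tr <- session$trials
  ref_tr <- tr$magnitude[tr$block == reference_block & tr$type == "startle_only"]
  assert_that(length(ref_tr) >= 1,
              "no startle-only trials in the reference block")
  ref <- mean(ref_tr)
  assert_that(ref != 0, "startle-only reference magnitude is zero")
  pp <- tr[tr$type == "prepulse", , drop = FALSE]
  pp$ppi <- (1 - pp$magnitude / ref) * 100
  deltas <- sort(unique(pp$prepulse_delta))
  out <- data.frame(
    prepulse_delta = deltas,
    ppi_mean = vapply(deltas, function(d) mean(pp$ppi[pp$prepulse_delta == d]),
                      numeric(1)),
    ppi_sem = vapply(deltas, function(d) {
      v <- pp$ppi[pp$prepulse_delta == d]
      if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
    }, numeric(1)),
    n = vapply(deltas, function(d) sum(pp$prepulse_delta == d), integer(1)))
  attr(out, "reference") <- ref
  attr(out, "trial_ppi") <- pp
  out
}

#' Fit the psychometric logistic and extract the FDT
#'
#' Three-parameter logistic in log-Delta-f with the floor fixed at 0:
#' \code{PPI(Df) = max_ppi / (1 + exp(-slope (log Df - log midpoint)))},
#' fitted to the mean PPI at each positive prepulse difference
#' (Levenberg-Marquardt, deterministic multi-start). The FDT is the
#' frequency difference at 50\% of total PPI — the fitted midpoint. Fits
#' with r2 < \code{r2_threshold} (0.7) or non-convergent fits are excluded.
#'
#' @param ppi_by_delta data.frame from [compute_ppi()].
#' @param r2_threshold exclusion cutoff on the fit r2.
#' @return object of class \code{fdt_result}: \code{fdt} (\% or NA),
#'   \code{max_ppi}, \code{slope}, \code{r2}, \code{excluded},
#'   \code{exclusion_reason}, \code{fitted} values.
#' @export
fit_fdt <- function(ppi_by_delta, r2_threshold = 0.7) {
  df <- ppi_by_delta[ppi_by_delta$prepulse_delta > 0, , drop = FALSE]
  assert_that(nrow(df) >= 4, "need at least 4 distinct positive prepulse deltas")
  x <- df$prepulse_delta; y <- df$ppi_mean

  logistic3 <- function(p) p[1] / (1 + exp(-p[2] * (log(x) - log(p[3]))))
  best <- NULL
  for (mid0 in x) {
    for (slope0 in c(1, 2, 4)) {
      fit <- tryCatch(
        minpack.lm::nls.lm(
          par = c(a = max(max(y), 1), b = slope0, m = mid0),
          fn = function(p) y - logistic3(p),
          lower = c(0, 1e-3, min(x) / 4),
          upper = c(200, 100, max(x) * 4),
          control = minpack.lm::nls.lm.control(maxiter = 500)),
        error = function(e) NULL)
      if (is.null(fit)) next
      rss <- sum(fit$fvec^2)
      if (is.null(best) || rss < best$rss) {
        best <- list(coef = as.list(fit$par), rss = rss,
                     fitted = logistic3(fit$par))
      }
    }
  }

  if (is.null(best)) {
    return(structure(list(ppi_by_delta = ppi_by_delta, fdt = NA_real_,
                          max_ppi = NA_real_, slope = NA_real_, r2 = NA_real_,
                          excluded = TRUE, exclusion_reason = "fit failure",
                          fitted = NULL), class = "fdt_result"))
  }
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - best$rss / ss_tot
  excluded <- !is.finite(r2) || r2 < r2_threshold
  structure(list(
    ppi_by_delta = ppi_by_delta,
    fdt = if (excluded) NA_real_ else best$coef$m,
    max_ppi = best$coef$a, slope = best$coef$b, r2 = r2,
    excluded = excluded,
    exclusion_reason = if (excluded) sprintf("r2 %.3f < %.2f", r2, r2_threshold)
                       else NA_character_,
    fitted = best$fitted), class = "fdt_result")
}

#' Acoustic startle response magnitude and habituation
#'
#' ASR = mean startle-only magnitude over blocks 2--4 (or block 3 only via
#' \code{blocks}); habituation ratio = block-4 mean / block-2 mean.
#'
#' @param session a \code{ppi_session}.
#' @param blocks blocks pooled for the ASR.
#' @return list(asr, habituation_ratio).
#' @export
compute_asr <- function(session, blocks = 2:4) {
  stopifnot(inherits(session, "ppi_session"))
  tr <- session$trials
  so <- tr[tr$type == "startle_only", , drop = FALSE]
  assert_that(any(so$block == 2) && any(so$block == 4),
              "blocks 2 and 4 must contain startle-only trials")
  asr <- mean(so$magnitude[so$block %in% blocks])
  hab <- mean(so$magnitude[so$block == 4]) / mean(so$magnitude[so$block == 2])
  list(asr = asr, habituation_ratio = hab)
}

#' Analyse one PPI session end to end
#'
#' @param session a \code{ppi_session}.
#' @param r2_threshold exclusion cutoff passed to [fit_fdt()].
#' @return \code{fdt_result} with the session ASR attached (\code{asr},
#'   \code{habituation_ratio}).
#' @export
analyze_ppi_session <- function(session, r2_threshold = 0.7) {
  ppi <- compute_ppi(session)
  res <- fit_fdt(ppi, r2_threshold = r2_threshold)
  asr <- compute_asr(session)
  res$asr <- asr$asr
  res$habituation_ratio <- asr$habituation_ratio
  res
}

#' Compare pre/post FDT and ASR across animals
#'
#' Matched-animal comparison of two condition lists (e.g., before and after
#' tone pairing): per-animal percent changes and cohort-level two-tailed
#' paired t tests on FDT and ASR. Animals excluded in either session are
#' dropped from both.
#'
#' @param pre,post lists of \code{fdt_result} objects, matched by position.
#' @return list: per-animal table, \code{fdt_change_pct} and
#'   \code{asr_change_pct} (mean percent change), \code{fdt_test} and
#'   \code{asr_test} (paired t), \code{n} animals analysed, \code{n_excluded}.
#' @export
compare_conditions <- function(pre, post) {
  assert_that(length(pre) == length(post), "pre and post must be matched lists")
  ok <- vapply(seq_along(pre), function(i) {
    !pre[[i]]$excluded && !post[[i]]$excluded
  }, logical(1))
  assert_that(sum(ok) >= 3, "fewer than 3 matched, non-excluded animals",
              class = "acxplast_insufficient_data")
  tab <- data.frame(
    animal = which(ok),
    fdt_pre = vapply(pre[ok], function(r) r$fdt, numeric(1)),
    fdt_post = vapply(post[ok], function(r) r$fdt, numeric(1)),
    asr_pre = vapply(pre[ok], function(r) r$asr %||% NA_real_, numeric(1)),
    asr_post = vapply(post[ok], function(r) r$asr %||% NA_real_, numeric(1)))
  tab$fdt_change_pct <- 100 * (tab$fdt_post - tab$fdt_pre) / tab$fdt_pre
  tab$asr_change_pct <- 100 * (tab$asr_post - tab$asr_pre) / tab$asr_pre
  tidy_t <- function(a, b) {
    if (all(a == b)) return(list(statistic = 0, p = 1))
    tt <- stats::t.test(a, b, paired = TRUE)
    list(statistic = unname(tt$statistic), p = tt$p.value)
  }
  list(animals = tab,
       fdt_change_pct = mean(tab$fdt_change_pct),
       asr_change_pct = mean(tab$asr_change_pct),
       fdt_test = tidy_t(tab$fdt_pre, tab$fdt_post),
       asr_test = tidy_t(tab$asr_pre, tab$asr_post),
       n = sum(ok), n_excluded = sum(!ok))
}
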