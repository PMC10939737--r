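#' Difference-of-exponentials transient kernel
#'
#' Unit-peak transient shape used by the calcium-indicator simulator:
#' \deqn{k(t) = (e^{-t/\tau_d} - e^{-t/\tau_r}) / k_{max}, \quad t \ge 0}
#' with \eqn{\tau_r < \tau_d} and \eqn{k_{max}} chosen so the peak equals 1.
#' Zero for \code{t < 0}. Suits fast-rise indicators (jGCaMP8f-like), whose
#' 90--10\% decay exceeds the 10--90\% rise several-fold.
#'
#' @param t numeric vector of times (s), relative to transient onset.
#' @param tau_rise,tau_decay time constants (s), \code{tau_rise < tau_decay}.
#' @return numeric vector, unit peak.
#' @seealso [gamma_pulse()] for the slower adenosine transient shape.
#' @export
transient_kernel <- function(t, tau_rise, tau_decay) {
  assert_that(tau_rise > 0 && tau_decay > 0, "kernel time constants must be positive")
  assert_that(tau_rise < tau_decay, "tau_rise must be smaller than tau_decay")
  tp <- log(tau_decay / tau_rise) * tau_rise * tau_decay / (tau_decay - tau_rise)
  kmax <- exp(-tp / tau_decay) - exp(-tp / tau_rise)
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- (exp(-t[pos] / tau_decay) - exp(-t[pos] / tau_rise)) / kmax
  out
}

#' Gamma-shaped transient pulse
#'
#' Unit-peak pulse \eqn{k(t) = (t/t_p)^a e^{a(1 - t/t_p)}} for \eqn{t \ge 0},
#' peaking at \code{peak_time}. The shape parameter \code{a} decouples the
#' rising and falling limbs, so any decay/rise time ratio above 1 is
#' attainable — which the difference-of-exponentials family cannot do (its
#' 90--10\% decay is always at least ~5.9x the 10--90\% rise). Extracellular
#' adenosine transients rise and fall on comparable timescales, hence this
#' family models them.
#'
#' @param t numeric vector of times (s) relative to pulse onset.
#' @param shape positive shape parameter \code{a}.
#' @param peak_time time of the unit peak (s).
#' @return numeric vector, unit peak at \code{peak_time}, zero for \code{t <= 0}.
#' @export
gamma_pulse <- function(t, shape, peak_time) {
  assert_that(shape > 0, "pulse shape must be positive")
  assert_that(peak_time > 0, "pulse peak time must be positive")
  out <- numeric(length(t))
  pos <- t > 0
  x <- t[pos] / peak_time
  out[pos] <- exp(shape * (log(x) + 1 - x))
  out
}

#' Observable kinetics of a gamma pulse
#'
#' 10--90\% rise time (ascending limb) and 90--10\% decay time (descending
#' limb) of [gamma_pulse()], by root finding on the analytic curve.
#'
#' @inheritParams gamma_pulse
#' @return list with \code{rise}, \code{decay} and \code{peak_time} (s).
#' @export
pulse_kinetics <- function(shape, peak_time) {
  f <- function(t) gamma_pulse(t, shape, peak_time)
  up <- function(level) {
    stats::uniroot(function(t) f(t) - level, lower = peak_time * 1e-12,
                   upper = peak_time, tol = 1e-13)$root
  }
  down <- function(level) {
    hi <- peak_time * 2
    while (f(hi) > level) hi <- hi * 2
    stats::uniroot(function(t) f(t) - level, lower = peak_time, upper = hi,
                   tol = 1e-13)$root
  }
  list(rise = up(0.9) - up(0.1), decay = down(0.1) - down(0.9),
       peak_time = peak_time)
}

#' Time at which a gamma pulse first reaches a fraction of its peak
#'
#' @inheritParams gamma_pulse
#' @param frac fraction of the unit peak in [0, 1); 0 returns 0 (the pulse
#'   foot).
#' @return time (s) on the rising limb.
#' @export
pulse_threshold_time <- function(shape, peak_time, frac) {
  assert_that(frac >= 0 && frac < 1, "frac must lie in [0, 1)")
  if (frac == 0) return(0)
  stats::uniroot(function(t) gamma_pulse(t, shape, peak_time) - frac,
                 lower = peak_time * 1e-12, upper = peak_time,
                 tol = 1e-13)$root
}

.kernel_cache <- new.env(parent = emptyenv())

#' Solve gamma-pulse parameters from target rise and decay times
#'
#' Transient kinetics are reported as 10--90\% rise and 90--10\% decay times,
#' not shape parameters; this inverts [pulse_kinetics()] numerically so a
#' simulated pulse reproduces the reported observables.
#'
#' @param rise target 10--90\% rise time (s).
#' @param decay target 90--10\% decay time (s); must exceed \code{rise}.
#' @return list with \code{shape}, \code{peak_time} and the achieved
#'   \code{rise}/\code{decay} (s).
#' @export
solve_pulse_shape <- function(rise, decay) {
  assert_that(rise > 0 && decay > 0, "rise and decay targets must be positive")
  assert_that(decay > rise, "decay time must exceed rise time for this pulse family")
  key <- paste0(format(rise, digits = 12), "_", format(decay, digits = 12))
  hit <- .kernel_cache[[key]]
  if (!is.null(hit)) return(hit)
  start <- c(log(2), log(rise + decay))
  obj <- function(p) {
    kk <- pulse_kinetics(exp(p[1]), exp(p[2]))
    (log(kk$rise / rise))^2 + (log(kk$decay / decay))^2
  }
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  if (fit$value > 1e-12) {
    fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-15, maxit = 5000))
  }
  assert_that(fit$value < 1e-8, sprintf(
    "could not solve pulse shape for rise=%g s, decay=%g s", rise, decay))
  shape <- exp(fit$par[1]); tp <- exp(fit$par[2])
  kk <- pulse_kinetics(shape, tp)
  out <- list(shape = shape, peak_time = tp, rise = kk$rise, decay = kk$decay)
  .kernel_cache[[key]] <- out
  out
}
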