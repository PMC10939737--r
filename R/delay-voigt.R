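#' Pseudo-Voigt dip profile
#'
#' Five-parameter pseudo-Voigt used to describe how pairing-induced SEAR
#' reduction depends on the delay between sound and neuromodulatory
#' stimulation: a dip of depth \code{A} below offset \code{c}, mixing a
#' Lorentzian and a Gaussian of common centre \code{mu} and half-width
#' \code{w}:
#' \deqn{f(\Delta t) = c - A [\eta L(\Delta t) + (1-\eta) G(\Delta t)]}
#' where \eqn{L = w^2 / ((\Delta t - \mu)^2 + w^2)} and
#' \eqn{G = \exp(-\ln 2 \, (\Delta t - \mu)^2 / w^2)}, both unit-peak with
#' half maximum at \eqn{|\Delta t - \mu| = w}.
#'
#' @param delay delays (s).
#' @param A dip depth (\% units).
#' @param mu dip centre (s).
#' @param w half-width at half-maximum (s), > 0.
#' @param eta Lorentzian fraction in [0, 1].
#' @param c offset (\%), the value far from the dip.
#' @return numeric vector.
#' @export
pseudo_voigt <- function(delay, A, mu, w, eta, c) {
  x <- (delay - mu) / w
  L <- 1 / (1 + x^2)
  G <- exp(-log(2) * x^2)
  c - A * (eta * L + (1 - eta) * G)
}

#' Fit the pseudo-Voigt delay-dependence curve
#'
#' Nonlinear least squares (Levenberg-Marquardt via minpack.lm) with
#' deterministic multi-start initialization: \code{mu} from the argmin of the
#' data, \code{A} from the data range, \code{w} from a FWHM estimate, and
#' \code{eta} started at 0, 0.5 and 1. Bounds keep \code{w > 0} and
#' \code{eta} in [0, 1].
#'
#' @param delays delays (s); at least 5 distinct values spanning negative and
#'   positive delays.
#' @param values normalized SEAR (\% of baseline) at each delay.
#' @return object of class \code{pseudo_voigt_fit} with fields \code{A},
#'   \code{mu}, \code{w}, \code{eta}, \code{c}, \code{rss}, \code{fitted}.
#' @export
fit_delay_curve <- function(delays, values) {
  assert_that(length(delays) == length(values), "delays and values must be paired")
  assert_that(length(unique(delays)) >= 5, "need at least 5 distinct delays")
  assert_that(min(delays) < 0 && max(delays) > 0,
              "delays must span negative and positive values")

  mu0 <- delays[which.min(values)]
  c0 <- max(values)
  A0 <- max(c0 - min(values), 1e-6)
  # FWHM estimate: spread of the points lying below half-depth
  below <- delays[values < c0 - A0 / 2]
  w0 <- max(ifelse(length(below) > 1, diff(range(below)) / 2, NA),
            diff(range(delays)) / 20, na.rm = TRUE)

  resid_fn <- function(p) {
    values - pseudo_voigt(delays, p[1], p[2], p[3], p[4], p[5])
  }
  best <- NULL
  for (eta0 in c(0, 0.5, 1)) {
    for (wmul in c(0.5, 1, 2)) {
      fit <- tryCatch(
        minpack.lm::nls.lm(
          par = c(A = A0, mu = mu0, w = w0 * wmul, eta = eta0, c = c0),
          fn = resid_fn,
          lower = c(0, -Inf, 1e-9, 0, -Inf),
          upper = c(Inf, Inf, Inf, 1, Inf),
          control = minpack.lm::nls.lm.control(maxiter = 500)),
        error = function(e) NULL)
      if (is.null(fit)) next
      rss <- sum(fit$fvec^2)
      if (is.null(best) || rss < best$rss) {
        best <- as.list(fit$par)
        best$rss <- rss
      }
    }
  }
  assert_that(!is.null(best), "pseudo-Voigt fit failed to converge from all starts",
              class = "acxplast_fit_failure")
  best$fitted <- pseudo_voigt(delays, best$A, best$mu, best$w, best$eta, best$c)
  structure(best, class = "pseudo_voigt_fit")
}
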