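# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Linearly interpolated time at which `y` first crosses `level` going up
# (direction = 1) or down (direction = -1), scanning indices i0:i1.
# Returns NA_real_ when no crossing occurs.
crossing_time <- function(t, y, level, i0 = 1L, i1 = length(y), direction = 1L) {
  idx <- seq.int(i0, i1)
  yy <- y[idx]
  hit <- if (direction >= 0) yy >= level else yy <= level
  k <- which(hit)
  if (!length(k)) return(NA_real_)
  k <- k[1L]
  if (k == 1L) return(t[idx[1L]])
  ia <- idx[k - 1L]; ib <- idx[k]
  ya <- y[ia]; yb <- y[ib]
  if (yb == ya) return(t[ib])
  t[ia] + (level - ya) / (yb - ya) * (t[ib] - t[ia])
}

# log-linear interpolation of y over positive x, clamped at the range ends
loglin_interp <- function(x, xs, ys) {
  stopifnot(all(xs > 0), all(x > 0))
  o <- order(xs)
  stats::approx(log(xs[o]), ys[o], xout = log(x), rule = 2)$y
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg, class = "acxplast_error") {
  if (!isTRUE(cond)) stop(errorCondition(msg, class = c(class, "error")))
  invisible(TRUE)
}
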