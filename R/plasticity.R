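#' Tuning-frequency shift statistic
#'
#' \eqn{\Delta TF = |TF_{before} - f_{pair}| - |TF_{after} - f_{pair}|}:
#' positive values indicate a shift of the neuron's tuning toward the paired
#' tone, negative values a shift away from it. Antisymmetric under swapping
#' before/after.
#'
#' @param tf_before,tf_after tuning frequencies (kHz), vectorized.
#' @param f_pair pairing-tone frequency (kHz), e.g. 9.8.
#' @return numeric vector (kHz).
#' @export
delta_tf <- function(tf_before, tf_after, f_pair) {
  assert_that(all(tf_before > 0) && all(tf_after > 0) && all(f_pair > 0),
              "frequencies must be positive")
  abs(tf_before - f_pair) - abs(tf_after - f_pair)
}

#' Wilcoxon signed-rank test of a median-zero shift
#'
#' Two-sided signed-rank test of the Delta-TF sample against median 0.
#' Zeros are dropped (classic Wilcoxon convention) and their count logged.
#' Exact p via the signed-rank distribution when n <= 25 and the absolute
#' values are untied; otherwise a normal approximation with tie correction
#' and continuity correction. An all-zero sample is degenerate and returns
#' p = 1 with a flag.
#'
#' @param delta_tfs numeric vector of shift values (kHz).
#' @return list: \code{statistic} (V, sum of positive ranks), \code{z},
#'   \code{p}, \code{n} (nonzero count), \code{n_zero}, \code{method},
#'   \code{degenerate}.
#' @export
test_tf_shift <- function(delta_tfs) {
  x <- delta_tfs[!is.na(delta_tfs)]
  n_zero <- sum(x == 0)
  x <- x[x != 0]
  if (!length(x)) {
    return(list(statistic = NA_real_, z = NA_real_, p = 1, n = 0L,
                n_zero = n_zero, method = "degenerate", degenerate = TRUE))
  }
  assert_that(length(x) >= 5, "need at least 5 nonzero values")
  n <- length(x)
  r <- rank(abs(x))
  v <- sum(r[x > 0])
  ties <- any(duplicated(abs(x)))
  if (n <= 25 && !ties) {
    p <- min(1, 2 * min(stats::psignrank(v, n),
                        stats::psignrank(v - 1, n, lower.tail = FALSE)))
    method <- "exact"
    z <- NA_real_
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    cc <- sign(v - mu) * 0.5
    z <- (v - mu - cc) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(statistic = v, z = if (n <= 25 && !ties) NA_real_ else z, p = p,
       n = n, n_zero = n_zero, method = method, degenerate = FALSE)
}

#' Cumulative TF distributions and two-sample Kolmogorov-Smirnov test
#'
#' Empirical cumulative percentile distributions of the tuning frequencies
#' before and after training, with the two-sample KS statistic
#' \eqn{D = \sup_x |F_1(x) - F_2(x)|} computed over all pooled thresholds and
#' an asymptotic p-value (approximate in the presence of ties, which are
#' ubiquitous for grid-valued TFs).
#'
#' @param tfs_before,tfs_after TF samples (kHz), nonempty.
#' @return list: \code{curves} (data.frame tf, cdf_before, cdf_after over the
#'   pooled support), \code{D}, \code{p}, sample sizes.
#' @export
cumulative_tf_distributions <- function(tfs_before, tfs_after) {
  assert_that(length(tfs_before) >= 1 && length(tfs_after) >= 1,
              "both samples must be nonempty")
  xs <- sort(unique(c(tfs_before, tfs_after)))
  f1 <- stats::ecdf(tfs_before)(xs)
  f2 <- stats::ecdf(tfs_after)(xs)
  D <- max(abs(f1 - f2))
  n1 <- length(tfs_before); n2 <- length(tfs_after)
  ne <- n1 * n2 / (n1 + n2)
  p <- ks_asymptotic_p(sqrt(ne) * D)
  list(curves = data.frame(tf = xs, cdf_before = 100 * f1, cdf_after = 100 * f2),
       D = D, p = p, n_before = n1, n_after = n2)
}

# Kolmogorov asymptotic tail: Q(t) = 2 sum (-1)^{k-1} exp(-2 k^2 t^2)
ks_asymptotic_p <- function(t) {
  if (t <= 0) return(1)
  k <- seq_len(100)
  min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))))
}

#' Delta-TF transition heatmap
#'
#' Row-normalized transition matrix: cell (i, j) is the percentage of
#' neurons whose pre-training TF fell in bin i that ended in post-training
#' bin j. Rows with no neurons are zero and flagged unsampled. No TF change
#' in any neuron yields 100\% along the diagonal (slope = 1).
#'
#' @param tf_before,tf_after matched TF vectors (kHz).
#' @param grid frequency bins (kHz); every TF must be a member.
#' @return matrix (\%) with pre-TF rows and post-TF columns; attribute
#'   \code{unsampled} marks empty rows.
#' @export
build_delta_tf_heatmap <- function(tf_before, tf_after,
                                   grid = default_frequency_grid()) {
  assert_that(length(tf_before) == length(tf_after),
              "before/after TFs must be matched")
  assert_that(all(tf_before %in% grid) && all(tf_after %in% grid),
              "all TFs must be members of the bin grid")
  counts <- table(factor(tf_before, levels = grid),
                  factor(tf_after, levels = grid))
  row_n <- rowSums(counts)
  pct <- matrix(0, length(grid), length(grid),
                dimnames = list(grid, grid))
  nz <- row_n > 0
  pct[nz, ] <- 100 * counts[nz, , drop = FALSE] / row_n[nz]
  attr(pct, "unsampled") <- !nz
  attr(pct, "row_counts") <- as.vector(row_n)
  pct
}

#' Generate a synthetic tuning-plasticity experiment
#'
#' TF-level simulator for calibration and power studies of the shift
#' statistics: each neuron has a true TF on the stimulus grid; measured
#' before/after TFs add independent one-step measurement jitter (identical
#' law in both sessions, so the no-shift null makes before/after
#' exchangeable and Delta-TF symmetric about 0). A \code{shift_fraction} of
#' neurons moves 1--\code{max_shift_steps} grid steps toward the pairing
#' frequency in the after session.
#'
#' @param n_neurons matched neurons.
#' @param f_pair pairing frequency (kHz), a grid member.
#' @param shift_fraction fraction of neurons shifted toward \code{f_pair}
#'   (0 = null experiment).
#' @param grid frequency grid (kHz).
#' @param jitter_prob probability that a measured TF moves one grid step
#'   (direction symmetric, reflected at the grid edges).
#' @param max_shift_steps largest plasticity shift in grid steps.
#' @param seed integer seed.
#' @return data.frame: roi, tf_true, tf_before, tf_after, shifted.
#' @export
generate_plasticity_experiment <- function(n_neurons = 450, f_pair = 9.8,
                                           shift_fraction = 0,
                                           grid = default_frequency_grid(),
                                           jitter_prob = 0.2,
                                           max_shift_steps = 2, seed = 1L) {
  assert_that(f_pair %in% grid, "pairing frequency must lie on the grid")
  m <- length(grid)
  jitter_idx <- function(idx) {
    move <- stats::runif(n_neurons) < jitter_prob
    step <- ifelse(stats::runif(n_neurons) < 0.5, -1L, 1L)
    out <- idx + ifelse(move, step, 0L)
    # reflect at the edges
    out[out < 1L] <- 2L
    out[out > m] <- m - 1L
    out
  }
  with_seed(seed, {
    idx_true <- sample.int(m, n_neurons, replace = TRUE)
    shifted <- stats::runif(n_neurons) < shift_fraction
    ip <- match(f_pair, grid)
    idx_after_true <- idx_true
    steps <- sample.int(max_shift_steps, n_neurons, replace = TRUE)
    toward <- sign(ip - idx_true)
    idx_after_true[shifted] <- idx_true[shifted] +
      toward[shifted] * pmin(steps[shifted], abs(ip - idx_true[shifted]))
    data.frame(
      roi = seq_len(n_neurons),
      tf_true = grid[idx_true],
      tf_before = grid[jitter_idx(idx_true)],
      tf_after = grid[jitter_idx(idx_after_true)],
      shifted = shifted)
  })
}

#' Match two tuning sessions by ROI id
#'
#' Keeps neurons that are responsive, unsaturated and carry a TF in both
#' sessions; neurons responsive in only one session are counted and
#' reported, not silently dropped.
#'
#' @param before,after \code{tuning_result} objects over the same ROI set.
#' @return data.frame(roi, tf_before, tf_after) with attribute
#'   \code{n_one_session} (neurons responsive in exactly one session).
#' @export
match_tuning_sessions <- function(before, after) {
  stopifnot(inherits(before, "tuning_result"), inherits(after, "tuning_result"))
  ids <- intersect(before$roi_ids, after$roi_ids)
  ib <- match(ids, before$roi_ids); ia <- match(ids, after$roi_ids)
  ok_b <- before$responsive[ib] & !before$saturated[ib] & !is.na(before$tf[ib])
  ok_a <- after$responsive[ia] & !after$saturated[ia] & !is.na(after$tf[ia])
  both <- ok_b & ok_a
  out <- data.frame(roi = ids[both],
                    tf_before = before$tf[ib][both],
                    tf_after = after$tf[ia][both])
  attr(out, "n_one_session") <- sum(xor(ok_b, ok_a))
  out
}

#' Pre/post tuning-plasticity statistics
#'
#' Composes the Delta-TF statistic, the signed-rank shift test, the
#' cumulative-distribution KS comparison and the transition heatmap for a
#' matched set of neurons.
#'
#' @param matched data.frame(roi, tf_before, tf_after) (see
#'   [match_tuning_sessions()]), or two \code{tuning_result} objects passed
#'   as \code{before}/\code{after}.
#' @param f_pair pairing frequency (kHz).
#' @param grid frequency grid for the heatmap bins (the stimulus grid).
#' @param before,after alternative input: two \code{tuning_result}s.
#' @return object of class \code{plasticity_result}: per-neuron table with
#'   \code{delta_tf}, \code{wilcoxon}, \code{ks}, \code{heatmap},
#'   \code{cumulative} curves, \code{f_pair}, \code{n_neurons}.
#' @export
run_plasticity_pipeline <- function(matched = NULL, f_pair = 9.8,
                                    grid = default_frequency_grid(),
                                    before = NULL, after = NULL) {
  if (is.null(matched)) {
    assert_that(!is.null(before) && !is.null(after),
                "provide either a matched table or before/after tuning results")
    matched <- match_tuning_sessions(before, after)
  }
  assert_that(nrow(matched) >= 5, "fewer than 5 matched neurons",
              class = "acxplast_insufficient_data")
  matched$delta_tf <- delta_tf(matched$tf_before, matched$tf_after, f_pair)
  wil <- test_tf_shift(matched$delta_tf)
  ks <- cumulative_tf_distributions(matched$tf_before, matched$tf_after)
  hm <- build_delta_tf_heatmap(matched$tf_before, matched$tf_after, grid = grid)
  structure(list(
    neurons = matched, f_pair = f_pair, n_neurons = nrow(matched),
    n_one_session = attr(matched, "n_one_session") %||% NA_integer_,
    wilcoxon = wil, ks = list(D = ks$D, p = ks$p),
    cumulative = ks$curves, heatmap = hm), class = "plasticity_result")
}
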