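test_that("delta-TF follows the absolute-distance formula and is antisymmetric", {
  expect_equal(delta_tf(19.6, 9.8, 9.8), 9.8)
  expect_equal(delta_tf(9.8, 19.6, 9.8), -9.8)
  for (x in c(4.8, 9.8, 29.4)) expect_equal(delta_tf(x, x, 13.9), 0)
  withr::with_seed(51, {
    a <- runif(50, 4, 30); b <- runif(50, 4, 30)
    expect_equal(delta_tf(a, b, 9.8), -delta_tf(b, a, 9.8))
  })
})

test_that("signed-rank shift test behaves at the symmetric and one-sided extremes", {
  sym <- rep(c(-1, 1), 10) * (1:20 %% 7 + 1)
  expect_gt(test_tf_shift(sym)$p, 0.5)
  allpos <- rep(1, 20) + (1:20) / 100
  expect_lt(test_tf_shift(allpos)$p, 0.001)
  zeros <- rep(0, 10)
  r <- test_tf_shift(zeros)
  expect_true(r$degenerate)
  expect_equal(r$p, 1)
  expect_equal(r$n_zero, 10L)
})

test_that("signed-rank p matches exhaustive sign enumeration at n = 10", {
  withr::with_seed(52, {
    for (i in 1:5) {
      x <- round(rnorm(10, 0.3, 1), 3)
      x <- x[x != 0]
      if (length(x) < 5 || any(duplicated(abs(x)))) next
      mine <- test_tf_shift(x)
      oracle <- oracle_signed_rank(x)
      expect_equal(mine$statistic, oracle$statistic)
      expect_equal(mine$p, oracle$p, tolerance = 1e-12)
      ref <- stats::wilcox.test(x, mu = 0, exact = TRUE)
      expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
    }
  })
})

test_that("large-sample signed-rank approximation tracks wilcox.test with ties", {
  withr::with_seed(53, {
    x <- sample(c(-2, -1, 1, 2, 3), 60, replace = TRUE) +
      sample(c(0, 0.5), 60, replace = TRUE)
    x <- x[x != 0]
    mine <- test_tf_shift(x)
    ref <- suppressWarnings(stats::wilcox.test(x, mu = 0, exact = FALSE,
                                               correct = TRUE))
    expect_equal(mine$statistic, unname(ref$statistic))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
  })
})

test_that("KS distance covers identical, disjoint and random samples", {
  expect_equal(cumulative_tf_distributions(1:10, 1:10)$D, 0)
  expect_equal(cumulative_tf_distributions(1:5, 6:10)$D, 1)
  withr::with_seed(54, {
    for (i in 1:10) {
      a <- sample(default_frequency_grid(), 30, replace = TRUE)
      b <- sample(default_frequency_grid(), 30, replace = TRUE,
                  prob = c(4, 3, 2, 1, 1, 1, 1, 1))
      r <- cumulative_tf_distributions(a, b)
      expect_equal(r$D, oracle_ks_d(a, b), tolerance = 1e-12)
    }
    # p-value sanity against the stock asymptotic two-sample test
    a <- rnorm(40); b <- rnorm(40, 1)
    r <- cumulative_tf_distributions(a, b)
    ref <- stats::ks.test(a, b, exact = FALSE)
    expect_equal(r$D, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(r$p, ref$p.value, tolerance = 1e-6)
  })
})

test_that("KS D is invariant under monotone transforms of the frequency axis", {
  withr::with_seed(55, {
    a <- sample(default_frequency_grid(), 25, replace = TRUE)
    b <- sample(default_frequency_grid(), 35, replace = TRUE)
    d_khz <- cumulative_tf_distributions(a, b)$D
    d_oct <- cumulative_tf_distributions(log2(a), log2(b))$D
    expect_equal(d_khz, d_oct, tolerance = 1e-12)
  })
})

test_that("transition heatmap rows are percentages that sum to 100", {
  grid <- default_frequency_grid()
  same <- sample(grid, 40, replace = TRUE)
  hm <- build_delta_tf_heatmap(same, same, grid)
  expect_equal(unname(diag(hm)[!attr(hm, "unsampled")]),
               rep(100, sum(!attr(hm, "unsampled"))))
  off <- hm; diag(off) <- 0
  expect_equal(sum(off), 0)

  to_pair <- rep(9.8, 40)
  hm2 <- build_delta_tf_heatmap(same, to_pair, grid)
  expect_true(all(hm2[!attr(hm2, "unsampled"), colnames(hm2) != "9.8"] == 0))

  withr::with_seed(56, {
    a <- sample(grid, 60, replace = TRUE)
    b <- sample(grid, 60, replace = TRUE)
    hm3 <- build_delta_tf_heatmap(a, b, grid)
    expect_equal(unname(hm3), unname(oracle_heatmap(a, b, grid)),
                 tolerance = 1e-12, ignore_attr = TRUE)
    rs <- rowSums(hm3)[!attr(hm3, "unsampled")]
    expect_equal(unname(rs), rep(100, length(rs)), tolerance = 1e-9)
  })
  expect_error(build_delta_tf_heatmap(c(5), c(9.8), grid), "members")
})

test_that("plasticity pipeline: identity input gives null statistics and a diagonal map", {
  grid <- default_frequency_grid()
  withr::with_seed(57, {
    tf <- sample(grid, 100, replace = TRUE)
  })
  res <- run_plasticity_pipeline(
    data.frame(roi = 1:100, tf_before = tf, tf_after = tf), f_pair = 9.8)
  expect_true(res$wilcoxon$degenerate)
  expect_equal(res$wilcoxon$p, 1)
  expect_equal(res$ks$D, 0)
  expect_equal(sum(res$heatmap) ,
               100 * sum(!attr(res$heatmap, "unsampled")))
  expect_error(
    run_plasticity_pipeline(data.frame(roi = 1:3, tf_before = tf[1:3],
                                       tf_after = tf[1:3])),
    class = "acxplast_insufficient_data")
})

test_that("the TF-level experiment generator is deterministic and marks shifts", {
  d1 <- generate_plasticity_experiment(n_neurons = 200, shift_fraction = 0.4,
                                       seed = 8)
  d2 <- generate_plasticity_experiment(n_neurons = 200, shift_fraction = 0.4,
                                       seed = 8)
  expect_identical(d1, d2)
  expect_gt(mean(d1$shifted), 0.3)
  expect_lt(mean(d1$shifted), 0.5)
  # without measurement jitter, shifted neurons strictly approach the
  # pairing tone and unshifted neurons stay put
  d3 <- generate_plasticity_experiment(n_neurons = 300, shift_fraction = 0.5,
                                       jitter_prob = 0, seed = 9)
  moved <- d3$shifted & d3$tf_true != 9.8
  expect_true(all(abs(d3$tf_after[moved] - 9.8) <
                    abs(d3$tf_before[moved] - 9.8)))
  expect_true(all(d3$tf_after[!d3$shifted] == d3$tf_before[!d3$shifted]))
})
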