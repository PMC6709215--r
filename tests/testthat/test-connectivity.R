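test_that("correlogram normalization and sign conventions hold", {
  set.seed(8)
  x <- rnorm(300)
  auto <- cross_correlogram(x, x)
  expect_equal(auto$values[auto$lags == 0], 1)
  anti <- cross_correlogram(x, -x)
  expect_equal(anti$values[anti$lags == 0], -1)
  expect_true(all(abs(auto$values) <= 1 + 1e-12))
  expect_error(cross_correlogram(rep(2, 50), rnorm(50)), "constant")
})

test_that("a delayed copy peaks at the planted lag, matching the
           double-sum oracle", {
  set.seed(12)
  x <- rnorm(400)
  y <- c(rep(0, 20), x[1:380]) + rnorm(400, sd = 0.01)
  cg <- cross_correlogram(x, y)
  # oracle: evaluate the definition at every lag, find the extremum
  oracle_vals <- vapply(cg$lags, function(tau) direct_rcoeff(x, y, tau),
                        numeric(1))
  expect_equal(cg$values, oracle_vals, tolerance = 1e-10)
  expect_equal(cg$lags[which.max(abs(cg$values))], -20)  # x leads y
})

test_that("correlograms are invariant to channel rescaling", {
  set.seed(13)
  x <- rnorm(200); y <- rnorm(200)
  a <- cross_correlogram(x, y)
  b <- cross_correlogram(7.3 * x, 7.3 * y)
  expect_equal(a$values, b$values, tolerance = 1e-12)
})

test_that("lag extrema split the correlogram by direction and mask", {
  cg <- toy_correlogram(50, list(c(-10, 0.8), c(-30, -0.5), c(15, 0.2)))
  ex <- lag_extrema(cg, lag_mask(2, 40))
  expect_equal(c(ex$fwd$abs, ex$fwd$max, ex$fwd$min), c(0.8, 0.8, 0.5))
  expect_equal(ex$fwd$max_lag, -10)
  expect_equal(ex$fwd$min_lag, -30)
  expect_equal(ex$rev$max, 0.2)

  # masked-out peak is invisible
  ex2 <- lag_extrema(cg, lag_mask(12, 40))
  expect_equal(ex2$fwd$max, 0)
  expect_equal(ex2$fwd$abs, 0.5)

  zero <- toy_correlogram(50)
  exz <- lag_extrema(zero, lag_mask(2, 40))
  expect_equal(unlist(exz$fwd[c("abs", "max", "min")]), rep(0, 3),
               ignore_attr = TRUE)
  expect_error(lag_extrema(zero, lag_mask(60, 80)), "mask excludes")
})

test_that("ABS decomposes as max(MAX, MIN) for every element (property)", {
  for (seed in 1:20) {
    cg <- toy_correlogram(40, lapply(1:6, function(i) {
      set.seed(seed * 100 + i)
      c(sample(c(-40:-2, 2:40), 1), runif(1, -1, 1))
    }))
    ex <- lag_extrema(cg, lag_mask(2, 40))
    expect_equal(ex$fwd$abs, max(ex$fwd$max, ex$fwd$min))
    expect_equal(ex$rev$abs, max(ex$rev$max, ex$rev$min))
  }
  # and at the window level of the matrix pipeline
  set.seed(77)
  W <- matrix(rnorm(4 * 100), 4)
  ex <- ictonet:::window_pair_extrema(W, lag_mask(2, 25))
  expect_equal(ex$abs, pmax(ex$max, ex$min))
})

test_that("IAAFT surrogates keep amplitudes exactly and the spectrum
           approximately", {
  set.seed(31)
  # AR(2)-like colored series
  x <- as.numeric(stats::arima.sim(list(ar = c(0.6, -0.3)), 256))
  s <- iaaft_surrogate(x, seed = 5)
  expect_identical(sort(s), sort(x))
  spec_x <- Mod(fft(x)); spec_s <- Mod(fft(s))
  rmse <- sqrt(mean((spec_x - spec_s)^2)) / sqrt(mean(spec_x^2))
  expect_lt(rmse, 0.1)

  s2 <- iaaft_surrogate(x, seed = 6)
  expect_false(identical(s, s2))
  expect_identical(sort(s2), sort(x))
  expect_identical(iaaft_surrogate(x, seed = 5), s)  # deterministic
  expect_identical(iaaft_surrogate(rep(1, 10)), rep(1, 10))
})

test_that("the analysis plan yields 21 windows and the printed test counts", {
  plan <- connectivity_plan(30, 4000)
  expect_equal(plan$n_windows, 21)
  expect_equal(length(plan$window_starts), 21)
  expect_equal(diff(plan$window_starts)[1], 100)  # 25 ms stride at 4 kHz
  expect_equal(plan$n_comparisons, 870)
  expect_equal(plan$n_surrogate_windows, 2100)
  expect_equal(plan$mask$min_lag, 8)
  expect_equal(plan$mask$max_lag, 1000)
  # non-representable window layout
  expect_error(connectivity_plan(4, 150), "not representable")
})

test_that("planted directed lag is recovered with the right direction", {
  hits <- vapply(1:10, function(seed) {
    seg <- delayed_pair_segment(fs = 200, delay = 12, seed = seed)
    res <- segment_connectivity(seg, fs = 200, method = "abs",
                                n_surrogate_sets = 10, seed = seed + 100)
    res$weights[1, 2] > res$weights[2, 1] && res$weights[1, 2] > 0
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("independent channels yield only sparse, weak spurious weights", {
  # Overlapping windows make the 21 per-element values correlated, so the
  # rank-sum test lets a few weak elements through even for independent
  # noise (real recordings likewise show nonzero background elements, which
  # is what the n_nonzero QC monitors). The surviving weights must be few
  # and far below planted-coupling scale.
  res <- t(vapply(1:12, function(seed) {
    set.seed(seed)
    seg <- matrix(rnorm(4 * 200), 4)
    m <- segment_connectivity(seg, fs = 200, method = "abs",
                              n_surrogate_sets = 10, seed = seed + 500)
    c(frac_nonzero = mean(m$weights[row(m$weights) != col(m$weights)] != 0),
      max_weight = max(m$weights))
  }, numeric(2)))
  expect_lt(mean(res[, "frac_nonzero"]), 0.3)
  expect_lt(max(res[, "max_weight"]), 0.3)
  # a genuine planted coupling is an order of magnitude stronger
  seg <- delayed_pair_segment(fs = 200, delay = 12, seed = 1)
  planted <- segment_connectivity(seg, fs = 200, method = "abs",
                                  n_surrogate_sets = 10, seed = 77)
  expect_gt(planted$weights[1, 2], 2 * max(res[, "max_weight"]))
})

test_that("zero-lag mixing alone produces no connection", {
  # channels share a source with no delay; mask starts at 8 samples
  set.seed(55)
  common <- rnorm(4000)
  seg <- rbind(common + rnorm(4000, sd = 0.2),
               0.8 * common + rnorm(4000, sd = 0.2))
  res <- segment_connectivity(seg, fs = 4000, method = "abs",
                              n_surrogate_sets = 8, seed = 9)
  expect_true(all(res$weights == 0))
})

test_that("matrices are scale invariant and properly normalized", {
  seg <- delayed_pair_segment(fs = 200, delay = 12, seed = 2)
  a <- segment_connectivity(seg, fs = 200, n_surrogate_sets = 8, seed = 3)
  b <- segment_connectivity(5 * seg, fs = 200, n_surrogate_sets = 8,
                            seed = 3)
  expect_equal(a$weights, b$weights, tolerance = 1e-10)

  ss <- structure(list(segments = list(seg, seg), fs = 200, n_segments = 2L,
                       layout = make_layout(1, 2)), class = "segment_set")
  rc <- recording_connectivity(ss, "abs", n_surrogate_sets = 8, seed = 4)
  expect_true(rc$normalized)
  expect_equal(sum(rc$weights), 1)
  expect_equal(diag(rc$weights), rep(0, 2))
  expect_equal(rc$n_segments_used, 2L)

  # all-zero degenerate case: normalization skipped
  set.seed(70)
  quiet <- structure(list(segments = list(matrix(rnorm(400), 2)), fs = 200,
                          n_segments = 1L, layout = make_layout(1, 2)),
                     class = "segment_set")
  rq <- recording_connectivity(quiet, "abs", n_surrogate_sets = 8, seed = 5)
  if (all(rq$weights == 0)) expect_false(rq$normalized)

  empty <- structure(list(segments = list(), fs = 200, n_segments = 0L),
                     class = "segment_set")
  expect_error(recording_connectivity(empty, "abs", seed = 1), "empty")
})

test_that("QC keeps recordings with enough segments and connections", {
  st <- data.frame(n_segments = c(55, 5, 20, 55),
                   n_nonzero = c(400, 400, 10, 50))
  expect_equal(qc_exclusion(st, 17, 50), c(TRUE, FALSE, FALSE, TRUE))
  expect_true(all(qc_exclusion(st, 0, 0)))
})
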