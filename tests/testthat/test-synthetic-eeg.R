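test_that("mirror grid layout pairs electrodes across the midline", {
  lay <- make_layout(5, 6)
  expect_equal(lay$n_channels, 30)
  p <- lay$contralateral_pair
  expect_equal(p[p], seq_len(30))            # involution
  expect_true(all(p != seq_len(30)))         # no self-pairing
  expect_equal(sum(lay$hemisphere == "left"),
               sum(lay$hemisphere == "right"))
  expect_equal(sum(seq_len(30) < p), 15)     # 15 distinct pairs
  # pairs mirror within the same row
  expect_equal(lay$positions[p, "y"], unname(lay$positions[, "y"]))
  expect_equal(lay$positions[p, "x"], unname(7 - lay$positions[, "x"]))

  tiny <- make_layout(1, 2)
  expect_equal(tiny$contralateral_pair, c(2L, 1L))
  expect_error(make_layout(2, 3), "even")
})

test_that("recording generation is deterministic and respects the mixing", {
  lay <- make_layout(1, 4)
  src <- data.frame(low = 1, high = 40, sd = 1)
  truth <- ground_truth_network(
    mixing = matrix(c(1, 0.8, 0, 0), 4, 1),
    lags = matrix(c(0, 40, 0, 0), 4, 1),
    sources = src, noise_sd = 0.05)
  r1 <- generate_recording(truth, lay, duration_s = 1, fs = 400, seed = 11)
  r2 <- generate_recording(truth, lay, duration_s = 1, fs = 400, seed = 11)
  expect_identical(r1$data, r2$data)

  # zero mixing: channels are independent sensor noise
  truth0 <- ground_truth_network(matrix(0, 4, 1), matrix(0, 4, 1), src,
                                 noise_sd = 1)
  r0 <- generate_recording(truth0, lay, duration_s = 2, fs = 400, seed = 3)
  cors <- cor(t(r0$data))
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.12)

  expect_error(generate_recording(truth, lay, duration_s = 0.05, fs = 400,
                                  seed = 1),
               "shorter than the longest")
})

test_that("a planted 40-sample lag difference shows up at |tau| = 40", {
  lay <- make_layout(1, 2)
  truth <- ground_truth_network(
    mixing = matrix(c(1, 0.9), 2, 1),
    lags = matrix(c(0, 40), 2, 1),
    sources = data.frame(low = 1, high = 150, sd = 1), noise_sd = 0.05)
  rec <- generate_recording(truth, lay, duration_s = 1, fs = 4000, seed = 7)
  x <- rec$data[1, ]; y <- rec$data[2, ]
  cg <- cross_correlogram(x, y, max_lag = 200)
  peak_lag <- cg$lags[which.max(abs(cg$values))]
  expect_lte(abs(abs(peak_lag) - 40), 1)
  # channel 1 leads channel 2: negative lag under the sign convention
  expect_lt(peak_lag, 0)
  # the FFT correlogram agrees with the direct double-sum definition
  for (tau in c(-40, -5, 0, 17)) {
    expect_equal(cg$values[cg$lags == tau], direct_rcoeff(x, y, tau),
                 tolerance = 1e-10)
  }
})

test_that("cohort stages plant the advertised symmetry structure", {
  lay <- make_layout(1, 6)
  d0 <- generate_cohort("day0", 2, seed = 21, layout = lay, fs = 200,
                        duration_s = 3)
  P <- lay$contralateral_pair
  for (rec in d0) {
    G <- truth_coupling(rec$truth)
    expect_equal(G, G[P, P])                   # commutes with the mirror
    expect_equal(nrow(rec$annotations), 0)     # no planted GS at day 0
  }
  sham <- generate_cohort("sham", 1, seed = 22, layout = lay, fs = 200,
                          duration_s = 3)
  Gs <- truth_coupling(sham[[1]]$truth)
  expect_equal(Gs, Gs[P, P])

  d28 <- generate_cohort("day28", 2, seed = 21, layout = lay, fs = 200,
                         duration_s = 3)
  for (rec in d28) {
    G <- truth_coupling(rec$truth)
    imb <- rowSums(G) - colSums(G)
    expect_gt(max(imb), 0)                     # planted source node exists
    expect_gt(sum(rec$annotations$event_type == "GS"), 0)
    expect_true(all(rec$annotations$onset_sample >= 0 &
                    rec$annotations$onset_sample < ncol(rec$data)))
  }

  expect_error(generate_cohort("day14", 2, seed = 1, layout = lay,
                               fs = 200, duration_s = 3),
               "unknown stage")
})

test_that("planted lags sit inside the retained lag band", {
  lay <- make_layout(1, 6)
  rec <- generate_cohort("day0", 1, seed = 5, layout = lay, fs = 4000,
                         duration_s = 1)[[1]]
  mask <- lag_mask_for_fs(4000)
  lags <- rec$truth$lags[rec$truth$lags > 0]
  expect_true(all(lags >= mask$min_lag & lags <= mask$max_lag))
})

test_that("recordings round-trip through CSV + JSON sidecar", {
  lay <- make_layout(1, 4)
  truth <- ground_truth_network(matrix(0, 4, 1), matrix(0, 4, 1),
                                data.frame(low = 1, high = 40, sd = 1))
  rec <- generate_recording(truth, lay, duration_s = 0.5, fs = 200,
                            seed = 2,
                            annotations = data.frame(event_type = "GS",
                                                     onset_sample = 10L))
  prefix <- file.path(tempdir(), "rec_roundtrip")
  write_recording(rec, prefix)
  back <- read_recording(prefix)
  expect_equal(back$data, rec$data, tolerance = 1e-12)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$annotations$onset_sample, 10L)
  expect_equal(back$layout$contralateral_pair, lay$contralateral_pair)
})
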