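test_that("burst segmentation follows the ISI-gap rule", {
  tr <- spike_train(c(0, 5, 10, 100, 105, 200) / 1000, duration = 0.3)
  seg <- segment_bursts(tr, isi_gap_threshold = 50)
  expect_equal(seg$burst_onsets, c(0, 0.1, 0.2))
  expect_equal(seg$spikes_per_burst, c(3L, 2L, 1L))
  expect_equal(sum(seg$spikes_per_burst), 6L)

  one <- segment_bursts(spike_train(0.5, 1))
  expect_equal(one$spikes_per_burst, 1L)
  empty <- segment_bursts(spike_train(numeric(0), 1))
  expect_length(empty$burst_onsets, 0)
  expect_error(segment_bursts(tr, 0), "positive")
})

test_that("burst segmentation is idempotent and offset-invariant", {
  set.seed(4)
  for (i in 1:5) {
    s <- sort(runif(30, 0, 2))
    tr <- spike_train(s, 2)
    seg <- segment_bursts(tr)
    shifted <- spike_train(s + 5, 8)
    seg2 <- segment_bursts(shifted)
    expect_equal(seg2$spikes_per_burst, seg$spikes_per_burst)
    expect_equal(seg2$burst_onsets, seg$burst_onsets + 5)
    # re-segmenting the burst onsets (ISIs all above threshold) is stable
    seg3 <- segment_bursts(spike_train(seg$burst_onsets, 2))
    expect_equal(seg3$burst_onsets, seg$burst_onsets)
  }
})

test_that("metrics report AFR, IBI and flags for degenerate trains", {
  tr <- spike_train(seq(0, 1.95, by = 0.05), 2)
  m <- compute_metrics(tr, 2)
  expect_equal(m$afr, 20)
  expect_equal(m$inst_rate$rate, rep(20, 39))

  m0 <- compute_metrics(spike_train(numeric(0), 2), 2)
  expect_equal(m0$afr, 0)
  expect_false(m0$ibi_defined)
  expect_true(is.na(m0$ibi_median))

  m1 <- compute_metrics(spike_train(0.3, 2), 2)
  expect_false(m1$ibi_defined)
})

test_that("noise-free median IBI matches SP/velocity for all five gratings", {
  by_sp <- noise_free_by_sp()
  expect_equal(nrow(by_sp), 5)
  expected_ms <- by_sp$sp / 10 * 1000
  expect_true(all(abs(by_sp$ibi_median - expected_ms) / expected_ms < 0.05))
})

test_that("spikes per burst follow the published coarseness gradient", {
  by_sp <- noise_free_by_sp()
  modal <- setNames(by_sp$modal_spb, sprintf("%.1f", by_sp$sp))
  expect_equal(modal[["0.5"]], 1)
  expect_true(modal[["1.0"]] %in% 2:3)
  expect_true(modal[["1.5"]] %in% 2:3)
  expect_gte(modal[["2.0"]], 4)
  expect_gte(modal[["3.0"]], 4)
  expect_true(all(diff(by_sp$modal_spb) >= 0))
})

test_that("spatial modulation index separates periodic from Poisson firing", {
  # single-spike-per-ridge comb at a coarse period: near the maximum of 2
  comb <- comb_train(0.3, 7)
  g <- grating_spec(3.0)
  smi_comb <- spatial_modulation_index(comb, g, 10)
  expect_gt(smi_comb, 1.7)
  expect_lte(smi_comb, 2)
  # rate-matched homogeneous Poisson trains score lower in expectation
  set.seed(8)
  smi_pois <- replicate(30, {
    s <- sort(runif(7, 0, 2))
    spatial_modulation_index(spike_train(s, 2), g, 10)
  })
  expect_lt(mean(smi_pois), smi_comb)
  expect_true(is.na(spatial_modulation_index(spike_train(numeric(0), 2), g, 10)))
})

test_that("spatial modulation rises monotonically with spatial period", {
  run <- default_run(20)
  sm <- aggregate(smi ~ sp, run$halves, mean)
  sm <- sm[order(sm$sp), ]
  expect_equal(nrow(sm), 5)
  expect_true(all(diff(sm$smi) > 0))
})

test_that("pair features carry signed differences and propagate flags", {
  nf <- noise_free_encodings()
  f00 <- pair_features(nf$D0.0$metrics[[1]], nf$D0.0$metrics[[2]],
                       nf$D0.0$pair)
  expect_equal(f00$delta_sp, 0)
  expect_lt(abs(f00$delta_ibi), 10)
  expect_lt(abs(f00$delta_afr), 2)

  f20 <- pair_features(nf$D2.0$metrics[[1]], nf$D2.0$metrics[[2]],
                       nf$D2.0$pair)
  expect_equal(f20$delta_ibi, 200, tolerance = 0.05)

  # the reversed order flips the sign of the features
  prot <- sliding_protocol()
  pairm <- make_stimulus_pair("D2.0", "-")
  encm <- encode_trial(synth_sensor_trace(pairm, prot, noise_free_calib(), seed = 1))
  m1 <- compute_metrics(encm$halves[[1]], 2)
  m2 <- compute_metrics(encm$halves[[2]], 2)
  fm <- pair_features(m1, m2, pairm)
  expect_equal(fm$delta_sp, -f20$delta_sp)
  expect_equal(fm$delta_ibi, -f20$delta_ibi, tolerance = 0.05)

  und <- compute_metrics(spike_train(numeric(0), 2), 2)
  fu <- pair_features(und, m2, pairm)
  expect_false(fu$ibi_defined)
  expect_true(is.na(fu$delta_ibi))
})

test_that("feature regression recovers exact and degenerate cases", {
  x <- c(-2, -1, 0, 1, 2)
  exact <- data.frame(delta_sp = x, delta_ibi = 10 * x, delta_afr = 5)
  r <- feature_vs_dsp_regression(exact, "delta_ibi")
  expect_equal(r$r_squared, 1)
  expect_equal(r$slope, 10)
  expect_equal(r$intercept, 0, tolerance = 1e-12)
  expect_equal(feature_vs_dsp_regression(exact, "delta_afr")$r_squared, 0)
  expect_error(feature_vs_dsp_regression(exact[1:2, ], "delta_ibi"),
               "3 distinct")
})

test_that("IBI separates spatial periods; equal groups do not separate", {
  set.seed(12)
  ibi <- c(rnorm(8, 50, 0.5), rnorm(8, 100, 0.5), rnorm(8, 150, 0.5))
  sp <- rep(c(0.5, 1, 1.5), each = 8)
  r <- ibi_specificity_test(ibi, sp)
  expect_lt(r$p_value, 1e-5)
  expect_true(r$all_separated)

  null <- ibi_specificity_test(rnorm(24, 100, 5), sp)
  expect_false(null$all_separated)

  expect_error(ibi_specificity_test(c(1, 2, 3), c(1, 2, 3)), "at least 2 trials")
})

test_that("default pipeline IBIs separate all ten SP pairs", {
  run <- default_run(10)
  r <- ibi_specificity_test(run$halves$ibi_median, run$halves$sp)
  expect_lt(r$p_value, 1e-5)
  expect_equal(nrow(r$pairs), 10)
  expect_true(r$all_separated)
})

test_that("metrics_table lays out one row per trial half", {
  nf <- noise_free_encodings()
  tab <- metrics_table(list(nf$D1.0$enc, nf$D2.5$enc))
  expect_equal(nrow(tab), 4)
  expect_equal(tab$sp, c(2.0, 1.0, 3.0, 0.5))
  expect_true(all(c("stimulus", "order", "ibi_median", "afr", "smi") %in% names(tab)))
})
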