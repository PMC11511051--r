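test_that("NN intervals derive from peaks with outlier rejection", {
  nn <- nn_intervals(c(0, 1, 2, 3))
  expect_equal(nn$nn, rep(1000, 3))

  # a 150 ms spurious interval is rejected and counted
  times <- c(0, 1, 2, 2.15, 3, 4)
  nn2 <- nn_intervals(times)
  expect_false(any(nn2$nn < 300))
  expect_gte(attr(nn2, "n_rejected"), 1L)

  expect_error(nn_intervals(1.0), "insufficient")
})

test_that("time-domain parameters match closed forms", {
  # alternating 800/1200 with an even number of successive differences
  alt <- new_nn_series(cumsum(c(0, rep(c(800, 1200), 100), 800) / 1000))
  ht <- hrv_time(alt)
  expect_equal(ht$rmssd, 400, tolerance = 1e-6)
  expect_equal(ht$sdnn_printed, 400, tolerance = 1e-6)
  expect_equal(ht$pnn50, 100)
  expect_equal(ht$sd1, 400 / sqrt(2), tolerance = 1e-6)
  expect_equal(ht$sd1, ht$sdnn_printed / sqrt(2), tolerance = 1e-9)

  const <- new_nn_series((0:10) * 1.0)
  hc <- hrv_time(const)
  expect_equal(hc$mean_nn, 1000)
  expect_equal(hc$ecg_rate_mean, 60)
  expect_equal(hc$rmssd, 0)
  expect_equal(hc$sdnn_printed, 0)
  expect_equal(hc$pnn50, 0)
  expect_equal(hc$sd1, 0)

  # threshold edge: |d| = 40 <= 50 does not count for pNN50
  edge <- new_nn_series(cumsum(c(0, 1000, 1040, 1000) / 1000))
  expect_equal(hrv_time(edge)$pnn50, 0)

  expect_error(hrv_time(new_nn_series(c(0, 1, 2))), "at least 3")
})

test_that("difference-based metrics are invariant to time reversal", {
  set.seed(5)
  nnv <- 850 + rnorm(100, 0, 40)
  fwd <- new_nn_series(cumsum(c(0, nnv)) / 1000)
  rev <- new_nn_series(cumsum(c(0, rev(nnv))) / 1000)
  hf <- hrv_time(fwd); hr <- hrv_time(rev)
  for (p in c("rmssd", "sdnn_printed", "pnn50", "sd1", "mean_nn"))
    expect_equal(hf[[p]], hr[[p]], tolerance = 1e-9)
})

test_that("spectral power concentrates in the modulated band", {
  lf_nn <- generate_nn_series(400, mean_nn = 850, lf = c(0.10, 50),
                              hf = c(0.25, 0), jitter_sd = 0, seed = 6)
  f_lf <- hrv_freq(lf_nn)
  expect_gte(f_lf$lf / f_lf$total, 0.8)
  expect_gte(f_lf$frac_04_40, 0.8)

  hf_nn <- generate_nn_series(400, mean_nn = 850, lf = c(0.10, 0),
                              hf = c(0.25, 50), jitter_sd = 0, seed = 6)
  f_hf <- hrv_freq(hf_nn)
  expect_gte(f_hf$hf / f_hf$total, 0.8)
  expect_gte(f_hf$frac_04_40, 0.8)

  # band powers partition the total exactly
  mixed <- generate_nn_series(400, seed = 7)
  fm <- hrv_freq(mixed)
  expect_equal(fm$vlf + fm$lf + fm$hf + fm$vhf, fm$total,
               tolerance = 1e-6)

  # constant NN: numerically zero spectrum after mean removal
  const <- new_nn_series((0:200) * 0.85)
  expect_lt(hrv_freq(const)$total, 1e-6)

  short <- generate_nn_series(50, seed = 8)
  expect_error(hrv_freq(short), "too short")
})

test_that("NN amplitude spectrum peaks at the modulation frequency", {
  lf_nn <- generate_nn_series(400, mean_nn = 850, lf = c(0.10, 50),
                              hf = c(0.25, 0), jitter_sd = 0, seed = 9)
  sp <- nn_fft_amplitude(lf_nn)
  peak_f <- sp$freq[which.max(sp$amplitude)]
  expect_lt(abs(peak_f - 0.10), sp$freq[2] - sp$freq[1] + 1e-9)

  # identical NN series give identical (perfectly correlated) curves
  sp2 <- nn_fft_amplitude(lf_nn)
  expect_equal(xcorr(sp$amplitude, sp2$amplitude, center = TRUE), 1.0)
})

test_that("random-slice comparison quantifies channel agreement", {
  # heteroscedastic series: beat-to-beat variability drifts over the
  # record, so variability parameters genuinely differ between slices
  set.seed(10)
  nnv <- 850 + rnorm(800, 0, seq(5, 40, length.out = 800))
  ecg_times <- cumsum(c(0, nnv)) / 1000
  pk <- structure(list(r_times = ecg_times), class = "bqc_peaks")
  cmp <- sliced_hrv_comparison(pk, pk, n_slices = 8, slice_len = 60,
                               seed = 11)
  expect_true(all(cmp$correlations == 1.0))

  # +/- 5 ms uniform timing jitter keeps parameters strongly correlated
  set.seed(12)
  pk_j <- structure(list(r_times = ecg_times +
                           runif(length(ecg_times), -0.005, 0.005)),
                    class = "bqc_peaks")
  cmp_j <- sliced_hrv_comparison(pk, pk_j, n_slices = 8, slice_len = 60,
                                 seed = 11)
  core <- cmp_j$correlations[c("mean_nn", "ecg_rate_mean", "rmssd",
                               "sdnn_printed", "sd1")]
  expect_true(all(core >= 0.9))

  expect_error(sliced_hrv_comparison(pk, pk, n_slices = 100, slice_len = 60),
               "cannot fit")
  # determinism under a fixed seed
  cmp2 <- sliced_hrv_comparison(pk, pk_j, n_slices = 8, slice_len = 60,
                                seed = 11)
  expect_identical(cmp_j$correlations, cmp2$correlations)
})
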