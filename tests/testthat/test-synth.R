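test_that("NN generator is deterministic with the stated moment structure", {
  a <- generate_nn_series(50, seed = 42)
  b <- generate_nn_series(50, seed = 42)
  expect_identical(a, b)
  c1 <- generate_nn_series(50, seed = 43)
  expect_false(identical(a$nn, c1$nn))

  # degenerate: no modulation, no jitter
  flat <- generate_nn_series(10, mean_nn = 1000, lf = c(0.1, 0),
                             hf = c(0.25, 0), jitter_sd = 0)
  expect_equal(flat$nn, rep(1000, 9))
  expect_equal(flat$beat_times, 0:9)

  # sinusoidal modulation averages out over many cycles
  m <- generate_nn_series(301, mean_nn = 1000, lf = c(0.1, 50),
                          hf = c(0.25, 0), jitter_sd = 0, seed = 1)
  expect_lt(abs(mean(m$nn) - 1000), 5)

  expect_error(generate_nn_series(40, mean_nn = 280, lf = c(0.1, 50),
                                  hf = c(0.25, 0), jitter_sd = 0),
               "non-physiologic")
})

test_that("synthetic ECG places R peaks exactly at ground-truth beat times", {
  ecg <- make_clean_ecg(duration = 30, seed = 2)
  truth <- attr(ecg, "r_times")
  fs <- ecg$fs
  for (b in truth) {
    idx <- round((b - 0.05) * fs):round((b + 0.05) * fs) + 1L
    local_max <- idx[which.max(ecg$samples[idx])]
    expect_lt(abs((local_max - 1) / fs - b), 0.002)
  }

  # degenerate morphology: only QRS deflections survive
  morph <- default_ecg_morphology()
  morph$amp_uv[morph$wave %in% c("P", "T")] <- 0
  nn <- generate_nn_series(10, jitter_sd = 0, lf = c(0.1, 0), hf = c(0.25, 0))
  qrs_only <- synthesize_ecg(nn, morph = morph)
  tt <- signal_times(qrs_only)
  far <- rep(TRUE, length(tt))
  for (b in attr(qrs_only, "r_times")) far <- far & abs(tt - b) > 0.08
  expect_lt(max(abs(qrs_only$samples[far])), 1)

  expect_error(synthesize_ecg(nn, fs = 200), "undersampled")
})

test_that("EMG bursts scale with force level and rest stays quiet", {
  ep <- data.frame(t_start = c(2, 6, 10), t_end = c(4, 8, 12), level = 1:3)
  x <- synthesize_emg(ep, duration = 14, seed = 3)
  r <- vapply(seq_len(3), function(i)
    rms(slice_signal(x, ep$t_start[i], ep$t_end[i])$samples), numeric(1))
  expect_true(all(diff(r) > 0))
  expect_equal(r / (50 * 1:3), rep(1, 3), tolerance = 0.15)
  expect_lt(rms(slice_signal(x, 0, 2)$samples), 2)

  quiet <- synthesize_emg(ep[0, ], duration = 5, seed = 3)
  expect_lt(rms(quiet$samples), 2)

  expect_identical(synthesize_emg(ep, duration = 14, seed = 3)$samples,
                   x$samples)
  bad <- data.frame(t_start = c(2, 3), t_end = c(4, 5), level = 1:2)
  expect_error(synthesize_emg(bad, duration = 6), "overlap")
})

test_that("EEG alpha power appears only during eyes-closed states", {
  tl <- data.frame(t_start = c(0, 30), t_end = c(30, 60),
                   state = c("eyes_closed", "eyes_open_calm"))
  x <- synthesize_eeg(tl, seed = 4)
  p_closed <- band_power(psd(slice_signal(x, 5, 25), demean = TRUE), 8, 13)
  p_open <- band_power(psd(slice_signal(x, 35, 55), demean = TRUE), 8, 13)
  expect_gt(10 * log10(p_closed / p_open), 6)

  # zero alpha amplitude: detector must report absence in both states
  x0 <- synthesize_eeg(tl, alpha_pp = 0, seed = 4)
  v <- alpha_detect(x0, data.frame(t_start = c(5, 35), t_end = c(25, 55)))
  expect_false(any(v$present))

  bad <- data.frame(t_start = c(0, 20), t_end = c(30, 50),
                    state = c("eyes_closed", "eyes_open_calm"))
  expect_error(synthesize_eeg(bad), "overlap")
})

test_that("noise injection hits the requested SNR exactly", {
  x <- make_tone(10, duration = 30)
  out <- add_noise(x, target_snr_db = 20, seed = 5)
  expect_equal(rms(out$noise) / rms(x$samples), 0.1, tolerance = 1e-6)
  expect_equal(out$achieved_snr_db, 20, tolerance = 1e-9)
  expect_equal(out$signal$samples - x$samples, out$noise, tolerance = 1e-12)

  # all components zero: infinite SNR flag
  clean <- add_noise(x, white_sd = 0)
  expect_identical(clean$achieved_snr_db, Inf)

  # deterministic components already louder than the target allows
  expect_error(add_noise(x, baseline = c(0.3, 5), target_snr_db = 40),
               "noise floor")

  # distinct seeds give distinct traces
  o2 <- add_noise(x, target_snr_db = 20, seed = 6)
  expect_false(identical(out$noise, o2$noise))
})

test_that("independent noise adds in variance (energy additivity)", {
  ecg <- make_clean_ecg(duration = 120, seed = 7)
  out <- add_noise(ecg, baseline = c(0.3, 5), powerline = c(60, 3),
                   target_snr_db = 25, seed = 8)
  v_clean <- var(ecg$samples)
  v_noise <- var(out$noise)
  v_noisy <- var(out$signal$samples)
  expect_equal(v_noisy, v_clean + v_noise, tolerance = 0.01)
})
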