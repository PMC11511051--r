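test_that("band-pass preserves the passband and rejects the stopband", {
  x10 <- make_tone(10, duration = 20)
  y10 <- bandpass(x10, 0.3, 100)
  gain_db <- 20 * log10(rms(y10$samples) / rms(x10$samples))
  expect_lt(abs(gain_db), 0.5)
  # zero-phase: in-band output stays aligned with the input
  expect_gt(xcorr(x10$samples, y10$samples), 0.999)

  drift <- make_tone(0.05, duration = 120)
  yd <- bandpass(drift, 0.3, 100)
  expect_lt(20 * log10(rms(yd$samples) / rms(drift$samples)), -20)

  x <- make_tone(50, duration = 20)
  expect_warning(yc <- bandpass(x, 10, 2000), "clipped")
  expect_lt(abs(rms(yc$samples) / rms(x$samples) - 1), 0.1)

  short <- bqc_signal(rnorm(100), fs = 1000)
  expect_error(bandpass(short, 0.3, 100), "too short")
})

test_that("notch removes the powerline tone and little else", {
  x60 <- make_tone(60, duration = 20)
  expect_lt(rms(notch(x60)$samples) / rms(x60$samples), 0.03)

  x10 <- make_tone(10, duration = 20)
  expect_lt(abs(rms(notch(x10)$samples) / rms(x10$samples) - 1), 0.02)

  for (f in c(50, 70)) {
    xf <- make_tone(f, duration = 20)
    att_db <- -20 * log10(rms(notch(xf)$samples) / rms(xf$samples))
    expect_lt(att_db, 3)
  }

  zero <- bqc_signal(numeric(2000), fs = 1000)
  expect_equal(notch(zero)$samples, numeric(2000), tolerance = 1e-12)

  expect_error(notch(make_tone(10, duration = 2, fs = 100), f0 = 60),
               "below fs/2")
})

test_that("R-peak detection recovers clean and noisy ground truth", {
  ecg <- make_clean_ecg(duration = 120, seed = 11)
  truth <- attr(ecg, "r_times")
  pk <- detect_r_peaks(preprocess_ecg(ecg))
  m <- match_peaks(pk$r_times, truth)
  expect_equal(m$sensitivity, 1.0)
  expect_equal(m$precision, 1.0)
  expect_lt(m$mean_abs_err_ms, 10)

  noisy <- add_noise(ecg, baseline = c(0.3, 10), powerline = c(60, 5),
                     target_snr_db = 20, seed = 12)$signal
  pk_n <- detect_r_peaks(preprocess_ecg(noisy))
  m_n <- match_peaks(pk_n$r_times, truth)
  expect_gte(m_n$sensitivity, 0.99)
  expect_gte(m_n$precision, 0.99)

  # refractory invariant
  expect_true(all(diff(pk$r_times) > 0.25))
})

test_that("R-peak detection is invariant to global amplitude scaling", {
  ecg <- make_clean_ecg(duration = 30, seed = 13)
  pre <- preprocess_ecg(ecg)
  scaled <- pre
  scaled$samples <- pre$samples * 1e3
  expect_identical(detect_r_peaks(pre)$r_indices,
                   detect_r_peaks(scaled)$r_indices)

  flat <- bqc_signal(numeric(10000), fs = 1000)
  expect_error(detect_r_peaks(flat), "no QRS")
  expect_error(detect_r_peaks(slice_signal(preprocess_ecg(ecg), 0, 4.5)),
               "too short")
})

test_that("delineation finds waves where the generator placed them", {
  ecg <- make_clean_ecg(duration = 60, seed = 14)
  pre <- preprocess_ecg(ecg)
  pk <- detect_r_peaks(pre)
  dl <- delineate_waves(pre, pk)
  morph <- default_ecg_morphology()
  cent <- function(w) morph$center_s[morph$wave == w]
  for (w in c("p", "q", "s", "t")) {
    off <- dl[[paste0(w, "_time")]] - dl$r_time
    err <- stats::median(abs(off - cent(toupper(w))), na.rm = TRUE)
    expect_lt(err, 0.010)
  }
  # ordering invariant on every beat where all waves are present
  full <- stats::complete.cases(dl[c("p_time", "q_time", "r_time",
                                     "s_time", "t_time")])
  expect_true(any(full))
  ord <- with(dl[full, ], p_time < q_time & q_time < r_time &
                r_time < s_time & s_time < t_time)
  expect_true(all(ord))
})

test_that("absent waves are marked absent, not invented", {
  # first beat too close to the record start for a P window
  nn <- generate_nn_series(20, jitter_sd = 0, lf = c(0.1, 0), hf = c(0.25, 0))
  ecg <- synthesize_ecg(nn, pad = 0.1)
  pre <- preprocess_ecg(ecg)
  pk <- detect_r_peaks(pre)
  dl <- delineate_waves(pre, pk)
  expect_true(is.na(dl$p_time[1]))

  # zero-amplitude P: detected "P" must be at noise level for most beats
  morph <- default_ecg_morphology()
  morph$amp_uv[morph$wave == "P"] <- 0
  nn2 <- generate_nn_series(60, seed = 15)
  ecg2 <- synthesize_ecg(nn2, morph = morph)
  pre2 <- preprocess_ecg(ecg2)
  dl2 <- delineate_waves(pre2, detect_r_peaks(pre2))
  # prominence above the inter-beat baseline (the high-passed trace sits
  # below zero between beats) must stay at noise level
  baseline <- stats::median(pre2$samples)
  small <- is.na(dl2$p_amp) | (dl2$p_amp - baseline) < 20
  expect_gte(mean(small), 0.9)
})
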