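test_that("kurtosis index matches analytic distribution values", {
  set.seed(1)
  gauss <- bqc_signal(rnorm(1e6), fs = 1000)
  expect_equal(ksqi(gauss), 3.0, tolerance = 0.1 / 3)
  expect_equal(ksqi(gauss, excess = TRUE), ksqi(gauss) - 3)

  sine <- make_tone(10, duration = 100)
  expect_equal(ksqi(sine), 1.5, tolerance = 0.05 / 1.5)

  expect_error(ksqi(bqc_signal(rep(1, 2000), fs = 1000)), "constant")
  expect_error(ksqi(bqc_signal(rnorm(500), fs = 1000)), "1000 samples")

  # clean synthetic ECG sits well above the excellence threshold
  ecg <- make_clean_ecg(duration = 60, seed = 21)
  expect_gt(ksqi(preprocess_ecg(ecg)), 5)
})

test_that("QRS-band relative power matches analytic band ratios", {
  expect_equal(psqi(make_tone(10, duration = 60)), 1.0, tolerance = 0.01)
  expect_lt(psqi(make_tone(30, duration = 60)), 0.01)

  set.seed(2)
  wn <- bqc_signal(rnorm(60000), fs = 1000)
  expect_equal(psqi(wn), 10 / 35, tolerance = 0.02 / (10 / 35))

  expect_error(psqi(make_tone(10, duration = 5)), "10 s")
})

test_that("baseline relative power matches analytic band ratios", {
  expect_gt(bassqi(make_tone(10, duration = 60)), 0.99)
  expect_lt(bassqi(make_tone(0.5, duration = 60)), 0.01)

  bl <- make_bandlimited_noise(duration = 120, hi = 40, seed = 3)
  expect_equal(bassqi(bl), 1 - 1 / 40, tolerance = 0.01 / 0.975)

  # amplitude-scaling invariance of both spectral indices
  ecg <- preprocess_ecg(make_clean_ecg(duration = 30, seed = 22))
  scaled <- ecg
  scaled$samples <- ecg$samples * 25
  expect_equal(psqi(scaled), psqi(ecg), tolerance = 1e-12)
  expect_equal(bassqi(scaled), bassqi(ecg), tolerance = 1e-12)
})

test_that("fuzzy evaluation reproduces the printed worked example", {
  triplets <- list(c(7.33, 0.67, 0.99), c(9.55, 0.71, 0.99),
                   c(8.85, 0.70, 0.99))
  res <- lapply(triplets, fuzzy_evaluate)
  vs <- vapply(res, `[[`, numeric(1), "v")
  expect_lt(max(vs) - min(vs), 1e-9)          # identical score for all three
  expect_equal(vs[1], 1.17, tolerance = 0.02 / 1.17)
  expect_true(all(vapply(res, `[[`, character(1), "grade") == "E"))
})

test_that("fuzzy score respects bounds, memberships and grade boundaries", {
  set.seed(4)
  for (i in 1:50) {
    tri <- c(runif(1, 1, 12), runif(1), runif(1))
    fz <- fuzzy_evaluate(tri)
    expect_true(all(fz$r >= 0 & fz$r <= 1))
    expect_true(all(fz$s >= 0 & fz$s <= 1))
    expect_gte(fz$v, 1)
    expect_lte(fz$v, 3)
    if (fz$s[2] > 0 || fz$s[3] > 0) expect_gt(fz$v, 1)
    if (fz$s[1] > 0 || fz$s[2] > 0) expect_lt(fz$v, 3)
  }
  # grade set boundaries exactly as printed
  expect_identical(grade_from_v(1.50), "E")
  expect_identical(grade_from_v(1.50 + 1e-9), "B")
  expect_identical(grade_from_v(2.40 - 1e-9), "B")
  expect_identical(grade_from_v(2.40), "U")

  # a triplet failing all three indices grades unacceptable
  expect_identical(fuzzy_evaluate(c(2.0, 0.10, 0.40))$grade, "U")
})

test_that("improving one index of a qualified record never raises the score", {
  v_of <- function(k, p, b) fuzzy_evaluate(c(k, p, b))$v
  ks <- seq(1, 10, by = 0.05)
  expect_true(all(diff(sapply(ks, v_of, p = 0.67, b = 0.99)) <= 1e-9))
  bs <- seq(0.3, 1, by = 0.005)
  expect_true(all(diff(sapply(bs, function(b) v_of(7.33, 0.67, b))) <= 1e-9))
  ps_up <- seq(0.05, 0.65, by = 0.005)
  expect_true(all(diff(sapply(ps_up, v_of, k = 7.33, b = 0.99)) <= 1e-9))
  ps_down <- seq(1.0, 0.65, by = -0.005)
  expect_true(all(diff(sapply(ps_down, v_of, k = 7.33, b = 0.99)) <= 1e-9))
})

test_that("decision workflow routes graded records as specified", {
  # Excellent: direct acceptance
  fz_e <- fuzzy_evaluate(c(7.33, 0.67, 0.99))
  expect_identical(quality_decision(fz_e), "accept")

  # Unacceptable with failing pSQI: re-record dominates
  fz_u <- fuzzy_evaluate(c(6, 0.3, 0.4))
  expect_identical(fz_u$grade, "U")
  expect_identical(quality_decision(fz_u), "rerecord")

  # Unacceptable with qualified pSQI: denoise and re-evaluate
  fz_u2 <- structure(list(grade = "U", triplet = c(2.0, 0.65, 0.40)),
                     class = "bqc_fuzzy")
  expect_identical(quality_decision(fz_u2), "denoise_and_reevaluate")

  # Barely acceptable: reassess once, then fall back to the U rules
  fz_b <- structure(list(grade = "B", triplet = c(4.0, 0.65, 0.93)),
                    class = "bqc_fuzzy")
  expect_identical(quality_decision(fz_b), "reassess")
  expect_identical(quality_decision(fz_b, rerun = TRUE),
                   "denoise_and_reevaluate")
  # reassessment that comes back Excellent is accepted
  expect_identical(quality_decision(fz_e, rerun = TRUE), "accept")
})
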