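# shared fixtures built in code

make_tone <- function(freq, duration = 20, fs = 1000, amp = 1,
                      modality = "OTHER", phase = 0) {
  tt <- (seq_len(round(duration * fs)) - 1L) / fs
  bqc_signal(amp * sin(2 * pi * freq * tt + phase), fs = fs,
             modality = modality)
}

make_clean_ecg <- function(duration = 120, seed = 1, mean_nn = 850,
                           fs = 1000, ...) {
  nn <- generate_nn_series(ceiling(duration * 1000 / mean_nn) + 2L,
                           mean_nn = mean_nn, seed = seed, ...)
  synthesize_ecg(nn, fs = fs)
}

# brick-wall band-limited white noise via FFT masking
make_bandlimited_noise <- function(duration = 120, fs = 1000, hi = 40,
                                   seed = 1) {
  set.seed(seed)
  n <- round(duration * fs)
  X <- stats::fft(stats::rnorm(n))
  f <- (seq_len(n) - 1L) * fs / n
  f <- pmin(f, fs - f)
  X[f >= hi] <- 0
  bqc_signal(Re(stats::fft(X, inverse = TRUE)) / n, fs = fs)
}

# peak matching against ground truth within a tolerance window
match_peaks <- function(detected, truth, tol = 0.15) {
  used <- logical(length(detected))
  tp <- 0L
  errs <- numeric(0)
  for (b in truth) {
    d <- abs(detected - b)
    j <- which.min(d)
    if (length(j) && d[j] <= tol && !used[j]) {
      tp <- tp + 1L
      used[j] <- TRUE
      errs <- c(errs, detected[j] - b)
    }
  }
  list(sensitivity = tp / length(truth),
       precision = tp / length(detected),
       mean_abs_err_ms = mean(abs(errs)) * 1000)
}

rms <- function(z) sqrt(mean((z - mean(z))^2))
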