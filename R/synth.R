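#' Generate a synthetic NN (beat-to-beat) interval series
#'
#' Beat intervals follow a mean heart period with sinusoidal modulation in
#' the low-frequency (LF, 0.04-0.15 Hz) and high-frequency (HF,
#' 0.15-0.4 Hz) autonomic bands plus Gaussian jitter:
#' \code{NN_k = mean_nn + lf_amp sin(2 pi f_lf t_k) +
#' hf_amp sin(2 pi f_hf t_k) + e_k}, where \code{t_k} is the cumulative
#' beat time and \code{e_k ~ N(0, jitter_sd^2)}.
#'
#' Defaults emulate a resting adult: mean heart period 850 ms
#' (about 71 bpm), respiratory sinus arrhythmia at 0.25 Hz and a
#' baroreflex-band oscillation at 0.10 Hz, with 10 ms beat jitter.
#'
#' @param n_beats Number of beats to generate.
#' @param mean_nn Mean NN interval in ms.
#' @param lf,hf Length-2 vectors \code{c(freq_hz, amplitude_ms)} of the
#'   LF and HF modulation components.
#' @param jitter_sd Standard deviation of the beat-to-beat jitter in ms.
#' @param seed Integer seed; fixed seed gives a reproducible series.
#' @return An object of class \code{bqc_nn} with fields
#'   \code{beat_times} (s, first beat at 0) and \code{nn} (ms,
#'   \code{length(beat_times) - 1} intervals).
#' @export
generate_nn_series <- function(n_beats, mean_nn = 850,
                               lf = c(freq = 0.10, amp = 30),
                               hf = c(freq = 0.25, amp = 20),
                               jitter_sd = 10, seed = 0) {
  stopifnot(n_beats >= 2, mean_nn > 0, lf[2] >= 0, hf[2] >= 0,
            jitter_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  eps <- rnorm(n_beats - 1L, 0, jitter_sd)
  beat_times <- numeric(n_beats)
  nn <- numeric(n_beats - 1L)
  t <- 0
  for (k in seq_len(n_beats - 1L)) {
    nn_k <- mean_nn + lf[[2]] * sin(2 * pi * lf[[1]] * t) +
      hf[[2]] * sin(2 * pi * hf[[1]] * t) + eps[k]
    if (nn_k <= 250)
      stop("non-physiologic NN interval (<= 250 ms) generated; ",
           "reduce modulation amplitudes or jitter")
    nn[k] <- nn_k
    t <- t + nn_k / 1000
    beat_times[k + 1L] <- t
  }
  new_nn_series(beat_times)
}

#' Construct an NN series from beat times
#'
#' @param beat_times Strictly increasing beat (R-peak) times in seconds.
#' @return A \code{bqc_nn} with \code{beat_times} (s) and \code{nn} (ms).
#' @export
new_nn_series <- function(beat_times) {
  beat_times <- as.numeric(beat_times)
  if (length(beat_times) < 2L) stop("need at least 2 beat times")
  if (any(diff(beat_times) <= 0)) stop("beat times must be strictly increasing")
  structure(list(beat_times = beat_times,
                 nn = diff(beat_times) * 1000,
                 t_nn = beat_times[-1L]),
            class = "bqc_nn")
}

#' @export
print.bqc_nn <- function(x, ...) {
  cat(sprintf("<bqc_nn> %d beats over %.1f s; mean NN %.1f ms\n",
              length(x$beat_times), diff(range(x$beat_times)), mean(x$nn)))
  invisible(x)
}

#' Default synthetic ECG morphology
#'
#' One Gaussian kernel per wave (P, Q, R, S, T), parameterized by
#' amplitude (microvolts), center offset relative to the R peak (s) and
#' kernel width (s, Gaussian sigma).
#'
#' @return A data.frame with columns \code{wave}, \code{amp_uv},
#'   \code{center_s}, \code{width_s}.
#' @export
default_ecg_morphology <- function() {
  data.frame(
    wave = c("P", "Q", "R", "S", "T"),
    amp_uv = c(150, -100, 1000, -150, 300),
    center_s = c(-0.20, -0.025, 0, 0.025, 0.30),
    width_s = c(0.025, 0.010, 0.012, 0.010, 0.060),
    stringsAsFactors = FALSE)
}

#' Synthesize an ECG trace from an NN series
#'
#' Places one Gaussian kernel per wave at each beat time. The returned
#' ground-truth R times equal the (padded) beat times exactly.
#'
#' @param nn A \code{bqc_nn} with at least 2 beats.
#' @param morph Morphology table as from [default_ecg_morphology()].
#' @param fs Sampling rate in Hz; must be at least 250.
#' @param pad Quiet padding in seconds added before the first and after
#'   the last beat.
#' @return A \code{bqc_signal} (modality ECG) with attribute
#'   \code{r_times} (s), the ground-truth R-peak times.
#' @export
synthesize_ecg <- function(nn, morph = default_ecg_morphology(), fs = 1000,
                           pad = 0.5) {
  stopifnot(inherits(nn, "bqc_nn"))
  if (fs < 250) stop("undersampled ECG: fs must be at least 250 Hz")
  if (any(morph$width_s <= 0)) stop("kernel widths must be positive")
  r <- morph$amp_uv[morph$wave == "R"]
  if (length(r) == 1 &&
      (r <= abs(morph$amp_uv[morph$wave == "Q"]) ||
       r <= abs(morph$amp_uv[morph$wave == "S"])))
    stop("R amplitude must exceed |Q| and |S| amplitudes")
  beats <- nn$beat_times + pad
  dur <- beats[length(beats)] + pad
  n <- round(dur * fs)
  tt <- (seq_len(n) - 1L) / fs
  x <- numeric(n)
  for (w in seq_len(nrow(morph))) {
    a <- morph$amp_uv[w]; off <- morph$center_s[w]; sg <- morph$width_s[w]
    if (a == 0) next
    for (b in beats) {
      c0 <- b + off
      i0 <- max(1L, floor((c0 - 5 * sg) * fs) + 1L)
      i1 <- min(n, ceiling((c0 + 5 * sg) * fs) + 1L)
      if (i1 < i0) next
      idx <- i0:i1
      x[idx] <- x[idx] + a * exp(-(tt[idx] - c0)^2 / (2 * sg^2))
    }
  }
  out <- bqc_signal(x, fs = fs, modality = "ECG", t0 = 0,
                    channel_label = "synthetic_ecg")
  attr(out, "r_times") <- beats
  out
}

#' Synthesize an EMG trace with force-graded activity bursts
#'
#' Broadband (20-450 Hz) zero-mean activity whose RMS inside each grip
#' epoch is proportional to the annotated force level
#' (\code{rms_per_level * level} microvolts) and near-zero at rest.
#'
#' @param epochs A data.frame with columns \code{t_start}, \code{t_end}
#'   (s, half-open, non-overlapping) and \code{level} (integer force
#'   level, 1-3).
#' @param duration Record duration in seconds.
#' @param fs Sampling rate in Hz.
#' @param rms_per_level Epoch RMS per unit force level, in microvolts.
#' @param baseline_rms Rest RMS in microvolts (<= 2 for a realistic
#'   resting muscle).
#' @param seed Integer seed.
#' @return A \code{bqc_signal} (modality EMG) with attribute
#'   \code{truth}: the epoch table with its target RMS values.
#' @export
synthesize_emg <- function(epochs, duration, fs = 1000, rms_per_level = 50,
                           baseline_rms = 1, seed = 0) {
  if (nrow(epochs)) {
    ep <- epochs[order(epochs$t_start), , drop = FALSE]
    if (any(ep$t_end <= ep$t_start)) stop("epochs must have t_end > t_start")
    if (nrow(ep) > 1 && any(ep$t_start[-1] < ep$t_end[-nrow(ep)]))
      stop("overlapping epochs")
    if (any(ep$t_start < 0) || any(ep$t_end > duration))
      stop("epochs outside record")
  } else ep <- epochs
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration * fs)
  raw <- rnorm(n)
  hi <- min(450, 0.45 * fs)
  flt <- signal::butter(2, c(20, hi) / (fs / 2), type = "pass")
  base <- .zero_phase(flt, raw)
  base <- base / sqrt(mean(base^2))  # unit-RMS broadband carrier
  gain <- rep(baseline_rms, n)
  tt <- (seq_len(n) - 1L) / fs
  if (nrow(ep)) {
    for (i in seq_len(nrow(ep))) {
      idx <- tt >= ep$t_start[i] & tt < ep$t_end[i]
      gain[idx] <- rms_per_level * ep$level[i]
    }
  }
  x <- base * gain
  out <- bqc_signal(x, fs = fs, modality = "EMG", t0 = 0,
                    channel_label = "synthetic_emg")
  if (nrow(ep)) ep$target_rms <- rms_per_level * ep$level
  attr(out, "truth") <- ep
  out
}

# pink-like (1/f amplitude) band-limited noise, unit RMS, via FFT shaping
.pink_noise <- function(n, fs, band = c(0.5, 45)) {
  X <- fft(rnorm(n))
  f <- (seq_len(n) - 1L) * fs / n
  f <- pmin(f, fs - f)  # two-sided frequency magnitude
  shape <- ifelse(f >= band[1] & f <= band[2], 1 / sqrt(pmax(f, band[1])), 0)
  x <- Re(fft(X * shape, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

#' Synthesize an EEG trace with state-dependent alpha rhythm
#'
#' A pink-like (1/f) background occupies 0.5-45 Hz throughout. During
#' \code{eyes_closed} epochs an amplitude-modulated alpha rhythm
#' (default 10 Hz) is added whose peak-to-peak amplitude stays within the
#' clinically typical 5-20 microvolt range. During
#' \code{eyes_open_moving} epochs, large low-frequency (< 4 Hz) eye
#' movement transients are added. \code{eyes_open_calm} epochs carry the
#' background only.
#'
#' @param timeline A data.frame with columns \code{t_start}, \code{t_end}
#'   (s, half-open, non-overlapping, tiling the record) and \code{state}
#'   in \code{c("eyes_closed", "eyes_open_calm", "eyes_open_moving")}.
#' @param fs Sampling rate in Hz.
#' @param alpha_freq Alpha rhythm frequency in Hz (8-13).
#' @param alpha_pp Nominal peak-to-peak alpha amplitude in microvolts;
#'   the slow (0.3 Hz) envelope modulation spans
#'   \code{alpha_pp * (1 +/- alpha_mod)}.
#' @param alpha_mod Relative depth of the alpha envelope modulation.
#' @param background_rms RMS of the pink background in microvolts.
#' @param artifact_amp Peak amplitude of eye-movement transients in
#'   microvolts.
#' @param seed Integer seed.
#' @return A \code{bqc_signal} (modality EEG) with attribute
#'   \code{truth}: the state timeline.
#' @export
synthesize_eeg <- function(timeline, fs = 1000, alpha_freq = 10,
                           alpha_pp = 12, alpha_mod = 0.25,
                           background_rms = 2, artifact_amp = 80, seed = 0) {
  st <- timeline[order(timeline$t_start), , drop = FALSE]
  if (any(st$t_end <= st$t_start)) stop("timeline epochs must have t_end > t_start")
  if (nrow(st) > 1 && any(st$t_start[-1] < st$t_end[-nrow(st)] - 1e-9))
    stop("overlapping timeline states")
  stopifnot(all(st$state %in%
                  c("eyes_closed", "eyes_open_calm", "eyes_open_moving")))
  duration <- max(st$t_end)
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration * fs)
  tt <- (seq_len(n) - 1L) / fs
  x <- background_rms * .pink_noise(n, fs)
  for (i in seq_len(nrow(st))) {
    idx <- which(tt >= st$t_start[i] & tt < st$t_end[i])
    if (!length(idx)) next
    if (st$state[i] == "eyes_closed" && alpha_pp > 0) {
      env <- (alpha_pp / 2) * (1 + alpha_mod * sin(2 * pi * 0.3 * tt[idx]))
      phase <- runif(1, 0, 2 * pi)
      x[idx] <- x[idx] + env * sin(2 * pi * alpha_freq * tt[idx] + phase)
    } else if (st$state[i] == "eyes_open_moving" && artifact_amp > 0) {
      # smooth high-amplitude deflections, ~1 per second, width 0.25 s
      k <- max(1L, round(diff(range(tt[idx]))))
      centers <- runif(k, st$t_start[i], st$t_end[i])
      signs <- sample(c(-1, 1), k, replace = TRUE)
      for (j in seq_len(k)) {
        x[idx] <- x[idx] + signs[j] * artifact_amp *
          exp(-(tt[idx] - centers[j])^2 / (2 * 0.25^2))
      }
    }
  }
  out <- bqc_signal(x, fs = fs, modality = "EEG", t0 = 0,
                    channel_label = "synthetic_eeg")
  attr(out, "truth") <- st
  out
}

#' Add structured noise to a clean signal
#'
#' The noise trace is the sum of sinusoidal baseline wander, a powerline
#' tone and white Gaussian noise. If \code{target_snr_db} is given, the
#' white component is scaled (given the actual sampled deterministic
#' components) so that the mean-removed RMS of the total noise trace
#' yields exactly the requested SNR in the sense
#' \code{SNR = 20 log10(rms(signal)/rms(noise))}.
#'
#' @param signal A clean \code{bqc_signal}; treated as ground truth.
#' @param baseline Length-2 vector \code{c(freq_hz, amplitude_uv)} of the
#'   baseline wander component (frequency should be below 0.5 Hz).
#' @param powerline Length-2 vector \code{c(freq_hz, amplitude_uv)}.
#' @param white_sd White noise standard deviation in microvolts; ignored
#'   (solved for) when \code{target_snr_db} is given.
#' @param target_snr_db Optional target SNR in dB.
#' @param seed Integer seed.
#' @return A list with \code{signal} (noisy \code{bqc_signal}),
#'   \code{noise} (the exact noise trace, numeric), and
#'   \code{achieved_snr_db} (\code{Inf} when all components are zero).
#' @export
add_noise <- function(signal, baseline = c(freq = 0.3, amp = 0),
                      powerline = c(freq = 60, amp = 0), white_sd = 0,
                      target_snr_db = NULL, seed = 0) {
  stopifnot(inherits(signal, "bqc_signal"))
  n <- length(signal$samples)
  tt <- signal_times(signal)
  det <- baseline[[2]] * sin(2 * pi * baseline[[1]] * tt) +
    powerline[[2]] * sin(2 * pi * powerline[[1]] * tt)
  if (!is.null(seed)) set.seed(seed)
  wht <- rnorm(n)
  rms0 <- function(z) sqrt(mean((z - mean(z))^2))
  sig_rms <- rms0(signal$samples)
  if (is.null(target_snr_db)) {
    noise <- det + white_sd * wht
  } else {
    target_rms <- sig_rms / 10^(target_snr_db / 20)
    dm <- det - mean(det)
    wm <- wht - mean(wht)
    A <- mean(wm^2)
    B <- 2 * mean(dm * wm)
    C <- mean(dm^2) - target_rms^2
    disc <- B^2 - 4 * A * C
    if (C > 0 && (disc < 0 || (-B + sqrt(disc)) / (2 * A) < 0))
      stop("noise floor exceeds target: deterministic components are ",
           "louder than the requested SNR allows")
    cc <- (-B + sqrt(max(disc, 0))) / (2 * A)
    noise <- det + cc * wht
  }
  nrms <- rms0(noise)
  achieved <- if (nrms == 0) Inf else 20 * log10(sig_rms / nrms)
  noisy <- bqc_signal(signal$samples + noise, fs = signal$fs,
                      modality = signal$modality, t0 = signal$t0,
                      channel_label = signal$channel_label)
  attr(noisy, "r_times") <- attr(signal, "r_times")
  list(signal = noisy, noise = noise, achieved_snr_db = achieved)
}
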