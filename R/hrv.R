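#' NN intervals from detected R peaks
#'
#' Successive R-peak differences in ms, with ectopy/outlier rejection:
#' intervals outside [300, 2000] ms or deviating more than 30 percent
#' from the running median of 5 are dropped (the count is kept in the
#' \code{n_rejected} attribute). Beat times of surviving intervals are
#' retained, so rejected beats open a gap rather than shifting time.
#'
#' @param peaks A \code{bqc_peaks} (or \code{bqc_nn}) with at least two
#'   peaks.
#' @param min_ms,max_ms Physiologic NN bounds in ms.
#' @param max_rel_dev Maximum allowed relative deviation from the running
#'   median of 5.
#' @return A \code{bqc_nn} with attribute \code{n_rejected}.
#' @export
nn_intervals <- function(peaks, min_ms = 300, max_ms = 2000,
                         max_rel_dev = 0.3) {
  times <- if (inherits(peaks, "bqc_peaks")) peaks$r_times
  else if (inherits(peaks, "bqc_nn")) peaks$beat_times
  else as.numeric(peaks)
  if (length(times) < 2L) stop("insufficient NN data: need at least 2 peaks")
  nn <- diff(times) * 1000
  k <- min(5L, length(nn))
  if (k %% 2L == 0L) k <- k - 1L
  runmed5 <- if (k >= 3L) stats::runmed(nn, k = k) else nn
  ok <- nn >= min_ms & nn <= max_ms & abs(nn - runmed5) <= max_rel_dev * runmed5
  n_rej <- sum(!ok)
  if (sum(ok) < 2L) stop("insufficient NN data after outlier rejection")
  out <- structure(list(beat_times = times,
                        nn = nn[ok],
                        t_nn = times[-1L][ok]),
                   class = "bqc_nn")
  attr(out, "n_rejected") <- n_rej
  out
}

#' Time-domain HRV parameters
#'
#' Computes, from the NN intervals (ms) and their successive differences
#' \code{d_k = nn_(k+1) - nn_k}:
#' \itemize{
#'   \item \code{mean_nn}: mean NN (ms), and \code{ecg_rate_mean}
#'     = 60000 / mean_nn (bpm);
#'   \item \code{rmssd}: root mean square of \code{d};
#'   \item \code{sdnn_printed}: the standard deviation of \code{d}
#'     (population form). Note this is the successive-difference
#'     dispersion (conventionally called SDSD); the conventional SDNN
#'     (standard deviation of the NN intervals themselves) is reported
#'     separately as \code{sdnn_conventional};
#'   \item \code{pnn50}: percentage of \code{|d| > 50} ms;
#'   \item \code{sd1}: Poincare minor-axis dispersion
#'     \code{sqrt(var(d)/2)}; with population variances
#'     \code{sd1 = sdnn_printed / sqrt(2)} exactly.
#' }
#'
#' @param nn A \code{bqc_nn} with at least 3 intervals.
#' @return Named list of the parameters above (all in ms, bpm or percent).
#' @export
hrv_time <- function(nn) {
  stopifnot(inherits(nn, "bqc_nn"))
  x <- nn$nn
  if (length(x) < 3L) stop("need at least 3 NN intervals")
  d <- diff(x)
  pvar <- function(z) mean((z - mean(z))^2)
  sdd <- sqrt(pvar(d))
  list(mean_nn = mean(x),
       ecg_rate_mean = 60000 / mean(x),
       rmssd = sqrt(mean(d^2)),
       sdnn_printed = sdd,
       sdnn_conventional = sqrt(pvar(x)),
       pnn50 = 100 * mean(abs(d) > 50),
       sd1 = sqrt(pvar(d) / 2))
}

# cubic-spline resampling of the NN series onto a uniform grid.
# Interval nn_k is anchored at the time of its ending beat.
.nn_anchor <- function(nn) {
  if (!is.null(nn$t_nn)) nn$t_nn else nn$beat_times[-1L]
}

.nn_resample <- function(nn, resample_fs) {
  t_nn <- .nn_anchor(nn)
  grid <- seq(t_nn[1L], t_nn[length(t_nn)], by = 1 / resample_fs)
  y <- spline(t_nn, nn$nn, xout = grid, method = "fmm")$y
  list(t = grid, y = y)
}

#' Frequency-domain HRV parameters
#'
#' The NN series is resampled to a uniform grid (default 4 Hz) by cubic
#' spline interpolation against beat times, mean-removed, and its power
#' spectrum estimated by averaged periodogram (Hann, 256-point segments,
#' 50 percent overlap). Band powers (ms^2) are binned sums over half-open
#' bands VLF [0, 0.04), LF [0.04, 0.15), HF [0.15, 0.4) and
#' VHF [0.4, Nyquist] Hz, so they sum exactly to the total.
#' \code{frac_04_40} = (LF + HF) / total is the fraction of power in the
#' 0.04-0.4 Hz band where a reliable recording concentrates its energy.
#'
#' @param nn A \code{bqc_nn} spanning at least 120 s.
#' @param resample_fs Uniform resampling rate in Hz.
#' @param nfft Spectral segment length in samples.
#' @param overlap Segment overlap fraction.
#' @return Named list with \code{vlf}, \code{lf}, \code{hf}, \code{vhf},
#'   \code{total} (ms^2) and \code{frac_04_40}.
#' @export
hrv_freq <- function(nn, resample_fs = 4, nfft = 256, overlap = 0.5) {
  stopifnot(inherits(nn, "bqc_nn"))
  if (diff(range(.nn_anchor(nn))) < 120)
    stop("record too short for HRV spectrum (< 120 s)")
  rs <- .nn_resample(nn, resample_fs)
  sp <- .welch_psd(rs$y, resample_fs, nfft, overlap, demean = TRUE)
  bp <- function(lo, hi) .band_power_bins(sp$freq, sp$psd, sp$df, lo, hi)
  vlf <- bp(0, 0.04); lf <- bp(0.04, 0.15); hf <- bp(0.15, 0.4)
  vhf <- bp(0.4, Inf)
  total <- vlf + lf + hf + vhf
  list(vlf = vlf, lf = lf, hf = hf, vhf = vhf, total = total,
       frac_04_40 = if (total > 0) (lf + hf) / total else 0)
}

#' Average FFT amplitude spectrum of the NN sequence
#'
#' After the same uniform resampling as [hrv_freq()], the record is split
#' into Hann-windowed segments (256 samples at 4 Hz, 50 percent overlap,
#' each mean-removed) and the single-sided FFT amplitude spectra are
#' averaged bin-wise, giving the average amplitude (ms) per frequency —
#' the curve used for visual and cross-channel comparison of HRV
#' spectra.
#'
#' @inheritParams hrv_freq
#' @return A data.frame with columns \code{freq} (Hz) and
#'   \code{amplitude} (ms).
#' @export
nn_fft_amplitude <- function(nn, resample_fs = 4, nfft = 256, overlap = 0.5) {
  stopifnot(inherits(nn, "bqc_nn"))
  if (diff(range(.nn_anchor(nn))) < 120)
    stop("record too short for HRV spectrum (< 120 s)")
  rs <- .nn_resample(nn, resample_fs)
  x <- rs$y
  if (length(x) < nfft) stop("record too short for HRV spectrum")
  w <- 0.5 * (1 - cos(2 * pi * (0:(nfft - 1)) / (nfft - 1)))
  hop <- max(1L, round(nfft * (1 - overlap)))
  starts <- seq(1L, length(x) - nfft + 1L, by = hop)
  nb <- nfft %/% 2 + 1L
  acc <- numeric(nb)
  for (s in starts) {
    seg <- x[s:(s + nfft - 1L)]
    seg <- seg - mean(seg)
    acc <- acc + Mod(fft(seg * w)[seq_len(nb)])
  }
  amp <- acc / length(starts) * 2 / sum(w)
  data.frame(freq = (seq_len(nb) - 1L) * resample_fs / nfft,
             amplitude = amp)
}

#' Random-slice HRV comparison of two channels
#'
#' Draws \code{n_slices} random non-overlapping windows of
#' \code{slice_len} seconds from the common time span (seeded rejection
#' sampling, at most 10^4 attempts, slices returned sorted), computes the
#' time-domain HRV parameters per channel per slice, and reports the
#' per-parameter cross-correlation (mean-centered normalized inner
#' product) between the channels across slices.
#'
#' @param peaks_a,peaks_b \code{bqc_peaks} covering the same time span.
#' @param n_slices Number of windows.
#' @param slice_len Window length in seconds.
#' @param seed Integer seed.
#' @return A list with \code{slices} (data.frame of window bounds),
#'   \code{params_a}, \code{params_b} (data.frames of per-slice HRV
#'   parameters) and \code{correlations} (named numeric vector).
#' @export
sliced_hrv_comparison <- function(peaks_a, peaks_b, n_slices = 10,
                                  slice_len = 60, seed = 0) {
  span_lo <- max(min(peaks_a$r_times), min(peaks_b$r_times))
  span_hi <- min(max(peaks_a$r_times), max(peaks_b$r_times))
  if (span_hi - span_lo < n_slices * slice_len)
    stop("span cannot fit the requested number of disjoint windows")
  if (!is.null(seed)) set.seed(seed)
  starts <- numeric(0)
  attempts <- 0L
  while (length(starts) < n_slices) {
    attempts <- attempts + 1L
    if (attempts > 1e4L)
      stop("could not place disjoint windows within 10^4 attempts")
    cand <- runif(1, span_lo, span_hi - slice_len)
    if (all(abs(cand - starts) >= slice_len)) starts <- c(starts, cand)
  }
  starts <- sort(starts)
  slice_params <- function(peaks, lo, hi) {
    keep <- peaks$r_times >= lo & peaks$r_times < hi
    if (sum(keep) < 4L) return(NULL)
    ht <- hrv_time(nn_intervals(peaks$r_times[keep]))
    unlist(ht)
  }
  rows_a <- list(); rows_b <- list()
  for (i in seq_along(starts)) {
    pa <- slice_params(peaks_a, starts[i], starts[i] + slice_len)
    pb <- slice_params(peaks_b, starts[i], starts[i] + slice_len)
    if (is.null(pa) || is.null(pb)) next
    rows_a[[length(rows_a) + 1L]] <- pa
    rows_b[[length(rows_b) + 1L]] <- pb
  }
  if (length(rows_a) < 3L)
    stop("fewer than 3 usable slices; increase span or shorten slices")
  pa <- as.data.frame(do.call(rbind, rows_a))
  pb <- as.data.frame(do.call(rbind, rows_b))
  cors <- vapply(names(pa), function(nm) {
    a <- pa[[nm]]; b <- pb[[nm]]
    if (isTRUE(all.equal(a, b))) return(1)  # identical incl. constant series
    tryCatch(suppressWarnings(xcorr(a, b, center = TRUE)),
             error = function(e) NA_real_)
  }, numeric(1))
  list(slices = data.frame(t_start = starts, t_end = starts + slice_len),
       params_a = pa, params_b = pb, correlations = cors)
}
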