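# Zero-phase filtering with odd-reflection end padding. Forward-backward
# application squares the magnitude response and cancels phase; padding
# suppresses the start/end transients of the recursive filter.
.zero_phase <- function(flt, x) {
  npad <- min(length(x) - 1L, 300L)
  pre <- 2 * x[1] - x[seq(npad + 1L, 2L)]
  post <- 2 * x[length(x)] - x[seq(length(x) - 1L, length(x) - npad)]
  y <- signal::filtfilt(flt, c(pre, x, post))
  y[(npad + 1L):(npad + length(x))]
}

#' Zero-phase band-pass filter
#'
#' Butterworth (maximally flat) design applied forward-backward, giving a
#' 4th-order magnitude response with zero phase distortion so that wave
#' timing is preserved for delineation. An upper edge at or above the
#' usable bandwidth is clipped to \code{0.45 * fs} with a warning (e.g.
#' the conventional 10-2000 Hz EMG band requested at fs = 1000 Hz).
#'
#' @param x A \code{bqc_signal}.
#' @param lo,hi Band edges in Hz, \code{0 <= lo < hi}. \code{lo = 0}
#'   yields a low-pass.
#' @param order Total filter order (must be even; forward-backward
#'   halves are \code{order/2}).
#' @return The filtered \code{bqc_signal}.
#' @export
bandpass <- function(x, lo, hi, order = 4) {
  stopifnot(inherits(x, "bqc_signal"), lo >= 0, hi > lo, order %% 2 == 0)
  fs <- x$fs
  hi_max <- 0.45 * fs
  if (hi > hi_max) {
    warning(sprintf("upper band edge %g Hz clipped to %g Hz (0.45 * fs)",
                    hi, hi_max))
    hi <- hi_max
    if (lo >= hi) stop("band collapsed after Nyquist clipping")
  }
  if (length(x$samples) < 3L * ceiling(3 * fs / max(lo, 1)))
    stop("record too short to filter at these band edges")
  flt <- if (lo <= 0) {
    signal::butter(order %/% 2, hi / (fs / 2), type = "low")
  } else {
    signal::butter(order %/% 2, c(lo, hi) / (fs / 2), type = "pass")
  }
  y <- .zero_phase(flt, x$samples)
  out <- x
  out$samples <- y
  out
}

#' Zero-phase powerline notch filter
#'
#' Narrow Butterworth band-stop of width \code{f0/q} centered on the
#' powerline frequency, applied forward-backward.
#'
#' @param x A \code{bqc_signal}.
#' @param f0 Notch center frequency in Hz (default 60).
#' @param q Quality factor; the stop band is \code{f0/q} Hz wide.
#' @return The filtered \code{bqc_signal}.
#' @export
notch <- function(x, f0 = 60, q = 30) {
  stopifnot(inherits(x, "bqc_signal"), q > 0)
  fs <- x$fs
  if (f0 >= fs / 2) stop("notch frequency must be below fs/2")
  bw <- f0 / q
  flt <- signal::butter(2, c(f0 - bw / 2, f0 + bw / 2) / (fs / 2),
                        type = "stop")
  out <- x
  out$samples <- .zero_phase(flt, x$samples)
  out
}

#' Standard ECG preprocessing
#'
#' Band-pass (default 0.3-100 Hz) plus powerline notch; the input for the
#' kurtosis and QRS-band power quality indices and for delineation. The
#' baseline index uses a notch-only copy instead, since band-passing
#' removes exactly the sub-1 Hz content it measures.
#'
#' @param x A \code{bqc_signal} (modality ECG).
#' @param config A [bqc_config()].
#' @return The preprocessed \code{bqc_signal}.
#' @export
preprocess_ecg <- function(x, config = bqc_config(fs = x$fs)) {
  b <- config$bands$ECG
  notch(bandpass(x, b[1], b[2]), config$notch$f0, config$notch$q)
}

# centered moving average via reflected padding (no NA edges)
.moving_avg <- function(y, w) {
  half <- (w - 1L) %/% 2L
  yp <- c(y[seq(half + 1L, 2L)], y, y[seq(length(y) - 1L, length(y) - half)])
  z <- stats::filter(yp, rep(1 / w, w), sides = 2)
  as.numeric(z[(half + 1L):(half + length(y))])
}

#' Detect R peaks with the two-moving-average method
#'
#' Knowledge-based QRS detection: band-pass 8-20 Hz, squaring, then two
#' moving averages — an event window (97 ms) tracking QRS energy and a
#' beat window (611 ms) tracking the local baseline — with an offset of
#' \code{beta} times the mean squared signal added to the beat average.
#' Contiguous blocks where the event average exceeds that threshold and
#' that are at least one event window wide yield one peak each (argmax of
#' the squared filtered energy; earliest sample wins ties). A 250 ms
#' refractory rule keeps the larger of two competing peaks. All
#' thresholds are relative, so detection is invariant to global
#' amplitude scaling.
#'
#' @param x A \code{bqc_signal}, nominally ECG, at least 5 s long.
#' @param band Detection band-pass edges in Hz.
#' @param w1_s,w2_s Event and beat moving-average window lengths in s.
#' @param beta Offset fraction of the mean squared filtered signal.
#' @param refractory_s Minimum peak spacing in seconds.
#' @return An object of class \code{bqc_peaks}: list with \code{r_times}
#'   (s, strictly increasing), \code{r_indices} (1-based sample indices)
#'   and \code{detector_meta}.
#' @export
detect_r_peaks <- function(x, band = c(8, 20), w1_s = 0.097, w2_s = 0.611,
                           beta = 0.08, refractory_s = 0.25) {
  stopifnot(inherits(x, "bqc_signal"))
  fs <- x$fs
  if (signal_duration(x) < 5) stop("record too short for QRS detection (< 5 s)")
  flt <- signal::butter(3, band / (fs / 2), type = "pass")
  xf <- .zero_phase(flt, x$samples)
  y <- xf^2
  if (max(y) <= 0 || sd(y) == 0) stop("no QRS detected")
  w1 <- round(w1_s * fs); if (w1 %% 2L == 0L) w1 <- w1 + 1L
  w2 <- round(w2_s * fs); if (w2 %% 2L == 0L) w2 <- w2 + 1L
  ma_event <- .moving_avg(y, w1)
  ma_beat <- .moving_avg(y, w2)
  thr <- ma_beat + beta * mean(y)
  active <- ma_event > thr
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  peaks <- integer(0)
  for (i in which(r$values)) {
    if (r$lengths[i] >= w1) {
      seg <- starts[i]:ends[i]
      peaks <- c(peaks, seg[which.max(y[seg])])
    }
  }
  if (!length(peaks)) stop("no QRS detected")
  refr <- refractory_s * fs
  keep <- peaks[1]
  for (p in peaks[-1]) {
    last <- keep[length(keep)]
    if (p - last > refr) keep <- c(keep, p)
    else if (y[p] > y[last]) keep[length(keep)] <- p
  }
  structure(list(
    r_times = x$t0 + (keep - 1L) / fs,
    r_indices = keep,
    detector_meta = list(band = band, w1 = w1, w2 = w2, beta = beta,
                         refractory_s = refractory_s)),
    class = "bqc_peaks")
}

#' @export
print.bqc_peaks <- function(x, ...) {
  cat(sprintf("<bqc_peaks> %d R peaks over [%.2f, %.2f] s\n",
              length(x$r_times), min(x$r_times), max(x$r_times)))
  invisible(x)
}

#' Delineate P, Q, S and T waves around detected R peaks
#'
#' Deterministic windowed extremum search relative to each R peak:
#' Q = minimum on [-60, -8] ms, S = minimum on [+8, +60] ms,
#' P = maximum on [-250, -80] ms, T = maximum on [+80, +400] ms with the
#' T window truncated at 55 percent of the current NN interval. Ties
#' resolve to the earliest sample. Windows that fall outside the record
#' mark the wave absent (NA) for that beat.
#'
#' @param x The preprocessed \code{bqc_signal} the peaks were detected on.
#' @param peaks A \code{bqc_peaks}.
#' @return A data.frame with one row per beat: \code{<wave>_time} (s) and
#'   \code{<wave>_amp} (microvolts) for P, Q, R, S, T.
#' @export
delineate_waves <- function(x, peaks) {
  stopifnot(inherits(x, "bqc_signal"), inherits(peaks, "bqc_peaks"))
  fs <- x$fs
  n <- length(x$samples)
  ri <- peaks$r_indices
  nb <- length(ri)
  win <- function(i, lo_ms, hi_ms) {
    a <- i + round(lo_ms / 1000 * fs)
    b <- i + round(hi_ms / 1000 * fs)
    if (a < 1L || b > n || b < a) return(NULL)
    a:b
  }
  pick <- function(idx, fun) {
    if (is.null(idx)) return(c(NA_real_, NA_real_))
    j <- idx[fun(x$samples[idx])]
    c(x$t0 + (j - 1L) / fs, x$samples[j])
  }
  out <- data.frame(beat = seq_len(nb))
  res <- matrix(NA_real_, nb, 10)
  for (k in seq_len(nb)) {
    i <- ri[k]
    nn_ms <- if (k < nb) (ri[k + 1L] - i) / fs * 1000 else Inf
    t_hi <- min(400, 0.55 * nn_ms)
    res[k, 1:2] <- pick(win(i, -250, -80), which.max)          # P
    res[k, 3:4] <- pick(win(i, -60, -8), which.min)            # Q
    res[k, 5:6] <- c(x$t0 + (i - 1L) / fs, x$samples[i])       # R
    res[k, 7:8] <- pick(win(i, 8, 60), which.min)              # S
    res[k, 9:10] <- pick(if (t_hi > 80) win(i, 80, t_hi) else NULL,
                         which.max)                            # T
  }
  cols <- c("p_time", "p_amp", "q_time", "q_amp", "r_time", "r_amp",
            "s_time", "s_amp", "t_time", "t_amp")
  out[cols] <- as.data.frame(res)
  out
}
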