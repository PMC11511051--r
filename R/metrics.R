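#' Signal-to-noise ratio of designated epochs
#'
#' \code{SNR = 20 log10(A_signal / A_noise)} where the amplitudes are the
#' root-mean-square values of the signal epoch and the noise epoch, each
#' after removal of its own mean (a DC electrode offset carries no signal
#' or noise power).
#'
#' @param signal_epoch A \code{bqc_signal} or numeric vector regarded as
#'   signal.
#' @param noise_epoch A \code{bqc_signal} or numeric vector regarded as
#'   noise; must have nonzero RMS.
#' @return An object of class \code{bqc_snr}: list with \code{snr_db},
#'   \code{a_signal_rms}, \code{a_noise_rms}.
#' @export
snr <- function(signal_epoch, noise_epoch) {
  s <- .coerce_samples(signal_epoch)
  n <- .coerce_samples(noise_epoch)
  if (!length(s) || !length(n)) stop("epochs must be non-empty")
  rms <- function(z) sqrt(mean((z - mean(z))^2))
  a_s <- rms(s)
  a_n <- rms(n)
  if (a_n == 0) stop("undefined SNR: noise epoch has zero RMS")
  structure(list(snr_db = 20 * log10(a_s / a_n),
                 a_signal_rms = a_s, a_noise_rms = a_n),
            class = "bqc_snr")
}

#' @export
print.bqc_snr <- function(x, ...) {
  cat(sprintf("<bqc_snr> %.2f dB (signal RMS %.3g, noise RMS %.3g)\n",
              x$snr_db, x$a_signal_rms, x$a_noise_rms))
  invisible(x)
}

#' Normalized cross-correlation of two equal-length segments
#'
#' The zero-lag normalized inner product
#' \deqn{\rho = \sum_i x_i y_i / \sqrt{\sum_i x_i^2 \sum_i y_i^2},}
#' computed literally by default (no mean removal, no lag search); a
#' value in [-1, 1] that equals 1 for identical or positively scaled
#' segments. With \code{center = TRUE} both inputs are mean-centered
#' first, which is the conventional choice when correlating spectra or
#' parameter vectors. Negative values (anti-correlated inputs) are
#' reported as-is, with a warning rather than clamping.
#'
#' @param x,y Equal-length numeric vectors or \code{bqc_signal}s, both
#'   with nonzero norm.
#' @param center Mean-center both inputs first.
#' @return The correlation coefficient (dimensionless).
#' @export
xcorr <- function(x, y, center = FALSE) {
  xv <- .coerce_samples(x)
  yv <- .coerce_samples(y)
  if (length(xv) != length(yv))
    stop("length mismatch: segments must have equal length")
  if (center) {
    xv <- xv - mean(xv)
    yv <- yv - mean(yv)
  }
  nx <- sqrt(sum(xv^2))
  ny <- sqrt(sum(yv^2))
  if (nx == 0 || ny == 0) stop("zero-norm input")
  rho <- sum(xv * yv) / (nx * ny)
  if (rho < 0) warning("negative cross-correlation (anti-correlated inputs)")
  rho
}

#' Per-epoch EMG burst metrics
#'
#' Computes the RMS and peak-to-peak amplitude (after per-epoch mean
#' removal) of each annotated grip epoch, and flags whether epoch RMS
#' increases strictly with the annotated force level. Levels whose mean
#' RMS values differ by no more than 5 percent are treated as equal, so
#' the flag requires a better-than-5-percent increase between
#' consecutive force levels; with a single distinct level the flag is
#' vacuously true.
#'
#' @param x A band-passed \code{bqc_signal} (modality EMG).
#' @param epochs A data.frame with columns \code{t_start}, \code{t_end}
#'   (s) and \code{level} (force level).
#' @return A list with \code{per_epoch} (data.frame: epoch bounds,
#'   level, \code{rms}, \code{peak_to_peak}, microvolts) and
#'   \code{monotonic} (logical).
#' @export
emg_burst_metrics <- function(x, epochs) {
  stopifnot(inherits(x, "bqc_signal"))
  hi <- x$t0 + signal_duration(x)
  if (any(epochs$t_start < x$t0 - 1e-9) || any(epochs$t_end > hi + 1e-9))
    stop("epoch outside record")
  res <- epochs
  res$rms <- NA_real_
  res$peak_to_peak <- NA_real_
  for (i in seq_len(nrow(epochs))) {
    ep <- slice_signal(x, epochs$t_start[i], epochs$t_end[i])
    z <- ep$samples - mean(ep$samples)
    res$rms[i] <- sqrt(mean(z^2))
    res$peak_to_peak[i] <- max(z) - min(z)
  }
  mono <- TRUE
  if (!is.null(epochs$level) && length(unique(epochs$level)) > 1L) {
    means <- tapply(res$rms, res$level, mean)
    means <- means[order(as.numeric(names(means)))]
    rel_gain <- diff(means) / head(means, -1)
    mono <- all(rel_gain > 0.05)
  }
  list(per_epoch = res, monotonic = mono)
}
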