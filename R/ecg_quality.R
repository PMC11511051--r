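# Averaged-periodogram (Welch) power spectral density. Hann-windowed
# segments with 50% overlap, window-power normalization, one-sided
# density in input-units^2 per Hz. The record mean (DC offset) is removed
# once before segmentation; segments are not individually detrended.
.welch_psd <- function(x, fs, nfft, overlap = 0.5, demean = TRUE) {
  x <- as.numeric(x)
  if (length(x) < nfft) stop("record shorter than one spectral segment")
  if (demean) x <- x - mean(x)
  w <- 0.5 * (1 - cos(2 * pi * (0:(nfft - 1)) / (nfft - 1)))
  hop <- max(1L, round(nfft * (1 - overlap)))
  starts <- seq(1L, length(x) - nfft + 1L, by = hop)
  nb <- nfft %/% 2 + 1L
  acc <- numeric(nb)
  for (s in starts) {
    X <- fft(x[s:(s + nfft - 1L)] * w)[seq_len(nb)]
    acc <- acc + Mod(X)^2
  }
  p <- acc / length(starts) / (fs * sum(w^2))
  if (nb > 2L) p[2:(nb - 1L)] <- 2 * p[2:(nb - 1L)]
  list(freq = (seq_len(nb) - 1L) * fs / nfft, psd = p,
       df = fs / nfft, n_segments = length(starts))
}

# Band power as a half-open binned sum: every frequency bin with
# lo <= f < hi contributes psd * df. Adjacent bands therefore partition
# the spectrum exactly (band powers sum to the total).
.band_power_bins <- function(freq, psd, df, lo, hi) {
  k <- freq >= lo & freq < hi
  sum(psd[k]) * df
}

#' Kurtosis signal quality index (kSQI)
#'
#' Pearson (non-excess) kurtosis \code{E[(x - mu)^4] / sigma^4} of the
#' preprocessed ECG trace. A Gaussian signal scores 3; the impulsive QRS
#' complexes of a clean ECG push it well above. The independent-indicator
#' rule classes the signal excellent when kSQI exceeds 5.
#'
#' @param x A \code{bqc_signal} (preprocessed ECG) or numeric vector of
#'   at least 1000 samples.
#' @param excess If \code{TRUE}, return excess kurtosis (Gaussian = 0)
#'   for sensitivity analysis.
#' @return Dimensionless kurtosis (>= 1 for any distribution).
#' @export
ksqi <- function(x, excess = FALSE) {
  z <- .coerce_samples(x)
  if (length(z) < 1000L) stop("kSQI needs at least 1000 samples")
  z <- z - mean(z)
  v <- mean(z^2)
  if (v == 0) stop("constant signal: kurtosis undefined")
  k <- mean(z^4) / v^2
  if (excess) k - 3 else k
}

#' QRS-band relative power index (pSQI)
#'
#' Ratio of spectral power in the QRS band [5, 15) Hz to the power in
#' [5, 40) Hz, from an averaged periodogram (Hann, 2048-sample segments,
#' 50 percent overlap at 1000 Hz). A clean adult ECG concentrates its
#' mid-band energy in the QRS complex; the qualifying region is
#' [0.5, 0.8].
#'
#' @param x A \code{bqc_signal} (preprocessed ECG), at least 10 s long.
#' @param nfft Spectral segment length in samples.
#' @param overlap Segment overlap fraction.
#' @return pSQI in [0, 1]. Invariant to global amplitude scaling.
#' @export
psqi <- function(x, nfft = 2048, overlap = 0.5) {
  stopifnot(inherits(x, "bqc_signal"))
  if (signal_duration(x) < 10) stop("pSQI needs at least 10 s of signal")
  sp <- .welch_psd(x$samples, x$fs, nfft, overlap)
  den <- .band_power_bins(sp$freq, sp$psd, sp$df, 5, 40)
  if (den <= 0) stop("no in-band power between 5 and 40 Hz")
  .band_power_bins(sp$freq, sp$psd, sp$df, 5, 15) / den
}

#' Baseline relative power index (basSQI)
#'
#' One minus the ratio of power in the baseline band [0, 1) Hz to power
#' in [0, 40) Hz; values near 1 indicate negligible baseline wander.
#' Computed on a minimally processed copy (powerline notch only) because
#' routine band-passing removes exactly the sub-1 Hz content measured
#' here. The record mean is removed first: a DC electrode offset is not
#' baseline wander.
#'
#' @inheritParams psqi
#' @return basSQI in [0, 1]. Invariant to global amplitude scaling.
#' @export
bassqi <- function(x, nfft = 2048, overlap = 0.5) {
  stopifnot(inherits(x, "bqc_signal"))
  if (signal_duration(x) < 10) stop("basSQI needs at least 10 s of signal")
  sp <- .welch_psd(x$samples, x$fs, nfft, overlap)
  den <- .band_power_bins(sp$freq, sp$psd, sp$df, 0, 40)
  if (den <= 0) stop("no in-band power between 0 and 40 Hz")
  1 - .band_power_bins(sp$freq, sp$psd, sp$df, 0, 1) / den
}

#' Compute the SQI triplet of an ECG record
#'
#' kSQI and pSQI are computed on the band-passed and notched trace
#' ([preprocess_ecg()]); basSQI on a notch-only copy of the raw record.
#'
#' @param x The raw \code{bqc_signal} (modality ECG).
#' @param config A [bqc_config()].
#' @return Named numeric vector \code{c(ksqi, psqi, bassqi)}.
#' @export
compute_sqi <- function(x, config = bqc_config(fs = x$fs)) {
  pre <- preprocess_ecg(x, config)
  raw_notched <- notch(x, config$notch$f0, config$notch$q)
  c(ksqi = ksqi(pre),
    psqi = psqi(pre, config$sqi_welch$nfft, config$sqi_welch$overlap),
    bassqi = bassqi(raw_notched, config$sqi_welch$nfft,
                    config$sqi_welch$overlap))
}

# --- membership functions ---------------------------------------------------

# Cauchy-type curve saturated to 1 at/above loc
.cauchy_up <- function(x, loc, scale) {
  ifelse(x >= loc, 1, 1 / (1 + ((x - loc) / scale)^2))
}
# shoulder: 1 at/below loc, Cauchy tail above, hard zero at/above cut
.cauchy_down <- function(x, loc, scale, cut = Inf) {
  ifelse(x >= cut, 0, ifelse(x <= loc, 1, 1 / (1 + ((x - loc) / scale)^2)))
}
.ramp_up <- function(x, a, b) pmin(1, pmax(0, (x - a) / (b - a)))
.ramp_down <- function(x, a, b) pmin(1, pmax(0, (b - x) / (b - a)))

.membership_matrix <- function(triplet, cfg) {
  k <- triplet[[1]]; p <- triplet[[2]]; b <- triplet[[3]]
  kk <- cfg$ksqi
  r_k <- c(.cauchy_up(k, kk$excellent[["loc"]], kk$excellent[["scale"]]),
           .cauchy_down(k, kk$barely[["loc"]], kk$barely[["scale"]],
                        cut = kk$qualify),
           .cauchy_down(k, kk$unacceptable[["loc"]],
                        kk$unacceptable[["scale"]], cut = kk$qualify))
  pe <- cfg$psqi$excellent; pb <- cfg$psqi$barely
  r_p <- c(as.numeric(p >= pe[1] & p <= pe[2]),
           as.numeric(p >= pb[1] & p <= pb[2]),
           as.numeric(p < pb[1] | p > pb[2]))
  bb <- cfg$bassqi
  r_b <- c(.ramp_up(b, bb$excellent[1], bb$excellent[2]),
           .ramp_down(b, bb$barely[1], bb$barely[2]),
           .ramp_down(b, bb$unacceptable[1], bb$unacceptable[2]))
  m <- rbind(ksqi = r_k, psqi = r_p, bassqi = r_b)
  colnames(m) <- c("excellent", "barely", "unacceptable")
  m
}

#' Map a quality score v to its grade
#'
#' Grade boundaries: Excellent (E) for \code{v <= 1.50}, Barely
#' acceptable (B) for \code{1.50 < v < 2.40}, Unacceptable (U) for
#' \code{v >= 2.40}.
#'
#' @param v Quality score in [1, 3].
#' @return One of \code{"E"}, \code{"B"}, \code{"U"}.
#' @export
grade_from_v <- function(v) {
  stopifnot(is.finite(v))
  if (v <= 1.50) "E" else if (v < 2.40) "B" else "U"
}

#' Fuzzy comprehensive evaluation of an SQI triplet
#'
#' Maps the three quality indices through per-level membership functions
#' (Cauchy-type for kSQI, rectangular for pSQI, trapezoidal shoulders for
#' basSQI; see [fuzzy_config_default()]), composes the fuzzy vector by
#' bounded sum \code{s_j = min(1, sum_i w_i r_ij)} over the three indices,
#' and aggregates to the score
#' \deqn{v = \sum_j s_j^2 j / \sum_j s_j^2,}
#' a squared-weighted average of the level indices (1 = excellent,
#' 2 = barely acceptable, 3 = unacceptable). The grade follows from
#' [grade_from_v()].
#'
#' @param triplet Numeric vector or list \code{(ksqi, psqi, bassqi)}, as
#'   from [compute_sqi()].
#' @param config A [fuzzy_config_default()]-style configuration.
#' @return An object of class \code{bqc_fuzzy}: list with the membership
#'   matrix \code{r} (3 indices x 3 levels), fuzzy vector \code{s},
#'   score \code{v}, and \code{grade}.
#' @export
fuzzy_evaluate <- function(triplet, config = fuzzy_config_default()) {
  triplet <- unlist(triplet)
  stopifnot(length(triplet) == 3, all(is.finite(triplet)))
  w <- config$weights
  stopifnot(abs(sum(w) - 1) < 1e-9)
  r <- .membership_matrix(triplet, config)
  s <- pmin(1, colSums(w * r))
  if (all(s == 0)) stop("degenerate membership: all fuzzy vector entries zero")
  v <- sum(s^2 * seq_len(3)) / sum(s^2)
  structure(list(r = r, s = s, v = v, grade = grade_from_v(v),
                 triplet = c(ksqi = triplet[[1]], psqi = triplet[[2]],
                             bassqi = triplet[[3]])),
            class = "bqc_fuzzy")
}

#' @export
print.bqc_fuzzy <- function(x, ...) {
  cat(sprintf("<bqc_fuzzy> v = %.4f  grade = %s  (kSQI %.2f, pSQI %.2f, basSQI %.2f)\n",
              x$v, x$grade, x$triplet[1], x$triplet[2], x$triplet[3]))
  invisible(x)
}

#' Quality decision workflow
#'
#' Routes a graded record:
#' \itemize{
#'   \item Grade E: \code{accept} — the signal can be used directly.
#'   \item Grade U: if pSQI lies outside its qualifying range the record
#'     must be \code{rerecord}ed (denoising cannot restore missing
#'     QRS-band power; this route dominates when several indices fail).
#'     Otherwise — kSQI at or below its threshold or basSQI below its
#'     bound indicates noise/artifacts — \code{denoise_and_reevaluate}.
#'   \item Grade B: \code{reassess} once; on the second pass
#'     (\code{rerun = TRUE}) a persistent B is handled by the U rules.
#' }
#'
#' @param result A \code{bqc_fuzzy} from [fuzzy_evaluate()].
#' @param triplet The SQI triplet the result was computed from; defaults
#'   to the one stored in \code{result}.
#' @param rerun Set \code{TRUE} when evaluating the repeated assessment
#'   of a B-graded record.
#' @param qualify Qualifying bounds, as in \code{bqc_config()$sqi_qualify}.
#' @return One of \code{"accept"}, \code{"denoise_and_reevaluate"},
#'   \code{"rerecord"}, \code{"reassess"}.
#' @export
quality_decision <- function(result, triplet = result$triplet, rerun = FALSE,
                             qualify = bqc_config()$sqi_qualify) {
  stopifnot(inherits(result, "bqc_fuzzy"))
  triplet <- unlist(triplet)
  g <- result$grade
  u_route <- function() {
    p_ok <- triplet[[2]] >= qualify$psqi_range[1] &&
      triplet[[2]] <= qualify$psqi_range[2]
    if (!p_ok) "rerecord" else "denoise_and_reevaluate"
  }
  if (g == "E") "accept"
  else if (g == "U") u_route()
  else if (!rerun) "reassess"
  else u_route()
}
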