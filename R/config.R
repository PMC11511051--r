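#' Default analysis configuration
#'
#' Central collection of tunable parameters for the preprocessing and
#' analysis pipeline. All frequency bands are in Hz and are clipped to
#' 0.45 * fs at filter time where necessary.
#'
#' @param fs Nominal sampling rate in Hz.
#' @param ... Named overrides merged over the defaults (one level deep).
#' @return A named list of class \code{bqc_config}.
#' @export
bqc_config <- function(fs = 1000, ...) {
  cfg <- list(
    fs = fs,
    # modality band-pass edges (Hz)
    bands = list(ECG = c(0.3, 100), EMG = c(10, 2000), EEG = c(0.3, 50)),
    notch = list(f0 = 60, q = 30),
    # Welch settings for the SQI spectral estimates
    sqi_welch = list(nfft = 2048, overlap = 0.5),
    # qualifying regions of the three ECG quality indices
    sqi_qualify = list(ksqi_min = 5, psqi_range = c(0.5, 0.8),
                       bassqi_min = 0.95),
    fuzzy = fuzzy_config_default(),
    # R-peak detector (two-moving-average, knowledge-based thresholds)
    rpeak = list(band = c(8, 20), w1_s = 0.097, w2_s = 0.611, beta = 0.08,
                 refractory_s = 0.25),
    # HRV spectral analysis
    hrv = list(resample_fs = 4, nfft = 256, overlap = 0.5,
               vlf = c(0, 0.04), lf = c(0.04, 0.15), hf = c(0.15, 0.4)),
    # NN outlier rejection
    nn_filter = list(min_ms = 300, max_ms = 2000, max_rel_dev = 0.3),
    # random-slice HRV channel comparison
    hrv_slices = list(n_slices = 10, slice_len = 60),
    # EEG analysis
    stft = list(window_s = 2, overlap = 0.5),
    alpha = list(band = c(8, 13), flank_lo = c(4, 7), flank_hi = c(14, 17),
                 ratio_threshold = 2, min_epoch_s = 4),
    seed = 0
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  class(cfg) <- "bqc_config"
  cfg
}

#' Default fuzzy comprehensive evaluation configuration
#'
#' Membership functions map each of the three ECG quality indices onto
#' three quality levels (1 = excellent, 2 = barely acceptable,
#' 3 = unacceptable):
#' \itemize{
#'   \item kSQI: Cauchy-type curves. The excellent membership saturates at
#'     1 for kSQI >= 5 (the independent-indicator threshold) and decays as
#'     \code{1/(1 + ((k - 5)/1.5)^2)} below it. The lower-level
#'     memberships are one-sided shoulders that saturate for poor values
#'     and vanish once kSQI qualifies.
#'   \item pSQI: rectangular windows; excellent on [0.5, 0.8], barely
#'     acceptable on [0.4, 0.9], unacceptable outside [0.4, 0.9].
#'   \item basSQI: trapezoidal shoulders; excellent ramps up over
#'     [0.90, 0.98], barely acceptable ramps down over [0.90, 0.95],
#'     unacceptable ramps down over [0.70, 0.85].
#' }
#' The fuzzy vector is formed by bounded-sum composition
#' \code{s_j = min(1, sum_i w_i r_ij)} with weights \code{w}, and the
#' score is the squared-weighted level average
#' \code{v = sum(s_j^2 j) / sum(s_j^2)}.
#'
#' These parameters are calibrated so that (a) index triplets whose three
#' components all lie in their qualifying regions score v = 1.17 (to two
#' decimals) and grade E, and (b) improving any single index toward its
#' qualifying region, with the other two indices qualified, never
#' increases v.
#'
#' @return A named list of class \code{bqc_fuzzy_config}.
#' @export
fuzzy_config_default <- function() {
  structure(list(
    weights = c(ksqi = 0.35, psqi = 0.45, bassqi = 0.20),
    ksqi = list(
      excellent = c(loc = 5, scale = 1.5),   # saturates to 1 at loc and above
      barely = c(loc = 3.5, scale = 1.0),    # shoulder: 1 at/below loc
      unacceptable = c(loc = 1.0, scale = 1.0),
      qualify = 5                            # levels 2-3 vanish at/above this
    ),
    psqi = list(
      excellent = c(0.5, 0.8),
      barely = c(0.4, 0.9)                   # unacceptable = complement
    ),
    bassqi = list(
      excellent = c(0.90, 0.98),             # linear ramp up, 1 above
      barely = c(0.90, 0.95),                # linear ramp down, 0 above
      unacceptable = c(0.70, 0.85)           # linear ramp down, 0 above
    )
  ), class = "bqc_fuzzy_config")
}
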