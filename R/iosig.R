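#' Construct a biopotential signal record
#'
#' A signal record holds a uniformly sampled biopotential trace in
#' microvolts together with its sampling rate, modality and start time.
#' Sample \code{i} (0-based) is located at time \code{t0 + i/fs} seconds.
#'
#' @param samples Numeric vector of sample values in microvolts. Must be
#'   finite and of length at least 2.
#' @param fs Sampling rate in Hz (positive).
#' @param modality One of \code{"ECG"}, \code{"EMG"}, \code{"EEG"},
#'   \code{"OTHER"}.
#' @param t0 Start time of the first sample in seconds.
#' @param channel_label Free-text channel label.
#' @return An object of class \code{bqc_signal}.
#' @export
bqc_signal <- function(samples, fs, modality = "OTHER", t0 = 0,
                       channel_label = "") {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("'fs' must be a single positive number")
  if (length(samples) < 2L)
    stop("signal must contain at least 2 samples")
  if (any(!is.finite(samples)))
    stop("signal samples must be finite (no NA/NaN/Inf)")
  modality <- match.arg(toupper(modality), c("ECG", "EMG", "EEG", "OTHER"))
  structure(
    list(samples = samples, fs = fs, modality = modality,
         t0 = as.numeric(t0), channel_label = as.character(channel_label)),
    class = "bqc_signal")
}

#' @export
print.bqc_signal <- function(x, ...) {
  cat(sprintf("<bqc_signal> %s  %d samples @ %g Hz  (%.3f s)  t0=%g s  %s\n",
              x$modality, length(x$samples), x$fs,
              signal_duration(x), x$t0, x$channel_label))
  invisible(x)
}

#' Duration of a signal record in seconds
#'
#' @param x A \code{bqc_signal}.
#' @return Duration \code{n/fs} in seconds.
#' @export
signal_duration <- function(x) {
  stopifnot(inherits(x, "bqc_signal"))
  length(x$samples) / x$fs
}

#' Sample times of a signal record
#'
#' @param x A \code{bqc_signal}.
#' @return Numeric vector of times \code{t0 + (0:(n-1))/fs} in seconds.
#' @export
signal_times <- function(x) {
  stopifnot(inherits(x, "bqc_signal"))
  x$t0 + (seq_along(x$samples) - 1L) / x$fs
}

.coerce_samples <- function(x) {
  if (inherits(x, "bqc_signal")) x$samples else as.numeric(x)
}

#' Read a biopotential trace from a delimited text file
#'
#' Accepts comma-, tab- or whitespace-delimited text with an optional
#' header row and either a single value column (uniform sampling implied;
#' \code{fs} is then required) or a time + value column pair
#' (\code{time_s}, \code{value_uV}). Values are interpreted as microvolts
#' unless \code{unit = "mV"}.
#'
#' @param path Path to the input file.
#' @param fs Sampling rate in Hz. Required for one-column files; for
#'   two-column files it defaults to the rate inferred from the time
#'   stamps, which must be uniform to within 1 percent jitter.
#' @param modality Signal modality label, see [bqc_signal()].
#' @param unit Input amplitude unit, \code{"uV"} (default) or \code{"mV"}.
#' @param channel_label Optional channel label; defaults to the file name.
#' @return A \code{bqc_signal}.
#' @export
read_signal <- function(path, fs = NULL, modality = "OTHER", unit = c("uV", "mV"),
                        channel_label = NULL) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty file: ", path)
  sep <- if (grepl(",", lines[[1]], fixed = TRUE)) "," else ""
  split1 <- strsplit(trimws(lines[[1]]), if (sep == ",") "," else "[ \t]+")[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(split1)))
  first_data <- if (has_header) 2L else 1L
  if (first_data > length(lines)) stop("no data rows in ", path)
  rows <- strsplit(trimws(lines[first_data:length(lines)]),
                   if (sep == ",") "," else "[ \t]+")
  ncol <- length(rows[[1L]])
  if (!ncol %in% c(1L, 2L))
    stop("expected 1 or 2 columns, found ", ncol, " in ", path)
  vals <- matrix(NA_real_, nrow = length(rows), ncol = ncol)
  for (i in seq_along(rows)) {
    r <- suppressWarnings(as.numeric(rows[[i]]))
    if (length(r) != ncol || anyNA(r) || any(!is.finite(r)))
      stop(sprintf("parse error at line %d of %s: '%s'",
                   first_data + i - 1L, path,
                   lines[first_data + i - 1L]))
    vals[i, ] <- r
  }
  if (is.null(channel_label)) channel_label <- basename(path)
  scale <- if (unit == "mV") 1000 else 1
  if (ncol == 1L) {
    if (is.null(fs)) stop("'fs' is required for one-column files")
    bqc_signal(vals[, 1] * scale, fs = fs, modality = modality, t0 = 0,
               channel_label = channel_label)
  } else {
    tcol <- vals[, 1]
    dt <- diff(tcol)
    if (any(dt <= 0)) stop("time stamps must be strictly increasing in ", path)
    med <- median(dt)
    if (any(abs(dt - med) > 0.01 * med))
      stop("non-uniform time stamps (jitter beyond 1%) in ", path)
    fs_inferred <- 1 / med
    if (is.null(fs)) fs <- fs_inferred
    bqc_signal(vals[, 2] * scale, fs = fs, modality = modality, t0 = tcol[1],
               channel_label = channel_label)
  }
}

#' Read event annotations from a delimited text file
#'
#' One annotation per row with columns \code{label}, \code{t_start},
#' \code{t_end} (seconds; comma- or tab-delimited, optional header).
#' Instant events use \code{t_start == t_end}; intervals are half-open
#' \code{[t_start, t_end)}.
#'
#' @param path Path to the annotation file.
#' @return A data.frame with columns \code{label}, \code{t_start},
#'   \code{t_end}.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (any(grepl(",", readLines(path, n = 1L), fixed = TRUE))) "," else ""
  df <- utils::read.table(path, sep = sep, header = FALSE,
                          col.names = c("label", "t_start", "t_end"),
                          stringsAsFactors = FALSE)
  if (is.character(df$t_start[1]) &&
      anyNA(suppressWarnings(as.numeric(df$t_start[1])))) {
    df <- df[-1L, , drop = FALSE]  # header row
  }
  df$t_start <- as.numeric(df$t_start)
  df$t_end <- as.numeric(df$t_end)
  if (anyNA(df$t_start) || anyNA(df$t_end))
    stop("non-numeric annotation times in ", path)
  if (any(df$t_start < 0) || any(df$t_end < df$t_start))
    stop("annotation intervals must satisfy 0 <= t_start <= t_end")
  rownames(df) <- NULL
  df
}

#' Extract a half-open time slice of a signal
#'
#' Sample \code{i} is included iff \code{t_start <= t(i) < t_end}. By
#' default the requested interval must lie inside the record; with
#' \code{clip = TRUE} it is clipped to the record extent instead.
#'
#' @param x A \code{bqc_signal}.
#' @param t_start,t_end Interval bounds in seconds (absolute time).
#' @param clip If \code{TRUE}, clip out-of-range intervals instead of
#'   raising an error.
#' @return A \code{bqc_signal} whose \code{t0} is the time of its first
#'   retained sample.
#' @export
slice_signal <- function(x, t_start, t_end, clip = FALSE) {
  stopifnot(inherits(x, "bqc_signal"))
  if (t_end <= t_start) stop("empty slice: t_end must exceed t_start")
  lo <- x$t0
  hi <- x$t0 + length(x$samples) / x$fs
  if (!clip && (t_start < lo - 1e-9 || t_end > hi + 1e-9))
    stop(sprintf("slice [%g, %g) outside record extent [%g, %g)",
                 t_start, t_end, lo, hi))
  t_start <- max(t_start, lo)
  t_end <- min(t_end, hi)
  # sample i (1-based) is at t0 + (i-1)/fs
  i0 <- ceiling((t_start - x$t0) * x$fs - 1e-9) + 1L
  i1 <- ceiling((t_end - x$t0) * x$fs - 1e-9)  # last sample strictly below t_end
  if (i1 < i0) stop("empty slice")
  if (i1 - i0 + 1L < 2L) stop("empty slice: fewer than 2 samples")
  bqc_signal(x$samples[i0:i1], fs = x$fs, modality = x$modality,
             t0 = x$t0 + (i0 - 1L) / x$fs, channel_label = x$channel_label)
}

#' Write a signal record to a delimited text file
#'
#' Writes \code{time_s,value_uV} rows (comma-separated, with header), the
#' canonical on-disk form read back by [read_signal()].
#'
#' @param x A \code{bqc_signal}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_signal <- function(x, path) {
  stopifnot(inherits(x, "bqc_signal"))
  df <- data.frame(time_s = signal_times(x), value_uV = x$samples)
  utils::write.table(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                     path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a quality report
#'
#' Serializes a (possibly nested) report of metric values to JSON at full
#' precision, and optionally emits a flat human-readable text summary next
#' to it. Sections that could not be computed should be stored as a list
#' with elements \code{computed = FALSE} and \code{reason}.
#'
#' @param report A named list of results (a \code{QualityReport}).
#' @param path Output path for the JSON report.
#' @param text_path Optional path for the human-readable summary; by
#'   default \code{path} with a \code{.txt} extension appended.
#' @param text Whether to write the text summary.
#' @return Invisibly, \code{path}.
#' @export
write_report <- function(report, path, text_path = paste0(path, ".txt"),
                         text = TRUE) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  if (text) {
    con <- file(text_path, "w")
    on.exit(close(con))
    writeLines(.report_lines(report, prefix = ""), con)
  }
  invisible(path)
}

.report_lines <- function(x, prefix = "") {
  out <- character(0)
  if (is.list(x)) {
    if (isFALSE(x$computed) && !is.null(x$reason)) {
      return(sprintf("%s: not computed (%s)", prefix, x$reason))
    }
    nms <- names(x)
    for (i in seq_along(x)) {
      nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
      p <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
      out <- c(out, .report_lines(x[[i]], p))
    }
  } else if (length(x) > 1L) {
    out <- sprintf("%s: [%s]", prefix,
                   paste(format(x, digits = 6), collapse = ", "))
  } else if (length(x) == 1L) {
    out <- sprintf("%s: %s", prefix,
                   if (is.numeric(x)) format(x, digits = 6) else as.character(x))
  }
  out
}

#' Read back a JSON quality report
#'
#' @param path Path written by [write_report()].
#' @return The report as a nested list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
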