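# Eleven hand-crafted features per repetition, per channel.
#
# Eight distribution features (min, max, mean, median, sd, variance,
# kurtosis, rms) plus three fatigue-oriented ones (skewness, IoP, MSP).
# All moments use the population (1/N) form. RMS is computed on deviations
# from the mean -- which makes it numerically equal to sd; a `rms_raw`
# switch computes sqrt(mean(x^2)) instead.

FEATURE_NAMES <- c("min", "max", "mean", "median", "sd", "variance",
                   "kurtosis", "rms", "skewness", "iop", "msp")

#' Nine distribution statistics of a series
#'
#' Population (1/N) estimators. Skewness and kurtosis are defined as 0 when
#' the series is constant (sd = 0) so features stay finite.
#'
#' @param x Numeric series, length >= 1.
#' @param rms_raw If `TRUE`, RMS is `sqrt(mean(x^2))`; by default it is
#'   computed on deviations from the mean and equals the population sd.
#' @return Named numeric vector: min, max, mean, median, sd, variance,
#'   kurtosis, rms, skewness.
#' @export
basic_stats <- function(x, rms_raw = FALSE) {
  n <- length(x)
  if (n < 1L) stop("basic_stats(): empty series", call. = FALSE)
  m <- sum(x) / n
  d <- x - m
  v <- sum(d^2) / n
  s <- sqrt(v)
  if (s > 0) {
    sk <- sum(d^3) / n / s^3
    ku <- sum(d^4) / n / s^4
  } else {
    sk <- 0
    ku <- 0
  }
  c(min = min(x), max = max(x), mean = m, median = stats::median(x),
    sd = s, variance = v, kurtosis = ku,
    rms = if (rms_raw) sqrt(sum(x^2) / n) else s,
    skewness = sk)
}

#' Peaks within one repetition
#'
#' Follows the same reference-channel convention as segmentation: the
#' series is smoothed with a short moving average and local maxima must
#' clear a prominence floor (a fraction of the repetition's smoothed
#' amplitude range) as well as lie strictly above the repetition mean, so
#' sub-movement/tremor bumps register while sample noise does not. The
#' global maximum is always included, so at least one peak is returned.
#'
#' @param x Series of one repetition (length >= 3).
#' @param timestamps Sample times in seconds, same length.
#' @param smoothing_window Moving-average width in samples (default 5, as
#'   in [segmentation_config()]).
#' @param prominence_fraction Prominence floor as a fraction of the
#'   smoothed repetition range (default 0.05).
#' @return List of class `peak_set` with `times` (strictly increasing) and
#'   `amplitudes` (read from the raw series), plus `indices` (1-based
#'   within the repetition).
#' @export
detect_peaks_in_rep <- function(x, timestamps, smoothing_window = 5L,
                                prominence_fraction = 0.05) {
  n <- length(x)
  if (n < 3L) stop("detect_peaks_in_rep(): need >= 3 samples", call. = FALSE)
  if (length(timestamps) != n) {
    stop("detect_peaks_in_rep(): timestamp length mismatch", call. = FALSE)
  }
  xs <- moving_average(x, min(smoothing_window, n))
  idx <- find_peaks(xs, min_distance = 1L,
                    min_prominence = prominence_fraction * diff(range(xs)))
  idx <- idx[x[idx] > mean(x)]
  gmax <- which.max(x)
  idx <- sort(unique(c(idx, gmax)))
  structure(list(times = timestamps[idx], amplitudes = x[idx],
                 indices = idx),
            class = "peak_set")
}

peak_set_at <- function(indices, x, timestamps) {
  structure(list(times = timestamps[indices], amplitudes = x[indices],
                 indices = indices),
            class = "peak_set")
}

#' Interval of peaks (IoP)
#'
#' Mean time between successive peaks; grows as fatigue slows the movement.
#' By convention 0 when fewer than two peaks are present.
#'
#' @param peaks A `peak_set`.
#' @return Mean inter-peak interval in seconds.
#' @export
interval_of_peaks <- function(peaks) {
  if (length(peaks$times) < 2L) return(0)
  mean(diff(peaks$times))
}

#' Mean slope between peaks (MSP)
#'
#' Average over all ordered pairs (i, j), i != j, of
#' `(p_j - p_i) / (T_j - T_i)`, normalized by N^2 (the diagonal 0/0 terms
#' are excluded from the sum while the printed 1/N^2 factor is kept).
#' Declines/flattens as fatigue erodes peak amplitudes.
#'
#' @param peaks A `peak_set`.
#' @return Slope in signal-units per second; 0 with fewer than two peaks.
#' @export
mean_slope_peaks <- function(peaks) {
  np <- length(peaks$times)
  if (np < 2L) return(0)
  if (anyDuplicated(peaks$times)) {
    stop("mean_slope_peaks(): duplicate peak times", call. = FALSE)
  }
  # (p_j - p_i) / (T_j - T_i) is invariant under swapping i and j, so the
  # ordered-pair sum is the elementwise off-diagonal sum of dp/dt.
  dp <- outer(peaks$amplitudes, peaks$amplitudes, "-")
  dt <- outer(peaks$times, peaks$times, "-")
  off <- row(dp) != col(dp)
  sum(dp[off] / dt[off]) / np^2
}

# Features of one repetition across the nine channels. Peaks are located
# once on the reference channel (same convention as segmentation) and the
# per-channel amplitudes are read off at those indices, so IoP is shared
# across channels while MSP is channel-specific.
rep_feature_row <- function(channels, timestamps, reference_channel = "gx",
                            rms_raw = FALSE) {
  ref_peaks <- detect_peaks_in_rep(channels[[reference_channel]], timestamps)
  out <- numeric(length(CHANNEL_NAMES_ALL) * length(FEATURE_NAMES))
  nms <- character(length(out))
  k <- 0L
  for (ch in CHANNEL_NAMES_ALL) {
    x <- channels[[ch]]
    ps <- peak_set_at(ref_peaks$indices, x, timestamps)
    vals <- c(basic_stats(x, rms_raw = rms_raw),
              iop = interval_of_peaks(ps),
              msp = mean_slope_peaks(ps))
    out[k + seq_along(vals)] <- vals
    nms[k + seq_along(vals)] <- paste(ch, FEATURE_NAMES, sep = "_")
    k <- k + length(vals)
  }
  stats::setNames(out, nms)
}

feature_colnames <- function() {
  as.vector(t(outer(CHANNEL_NAMES_ALL, FEATURE_NAMES, paste, sep = "_")))
}

#' Build the repetition-level feature table for a cohort
#'
#' One row per labeled repetition: metadata (`subject_id`, `hand`,
#' `set_index`, `rep_index`, `effective_rpe`, `label`) plus 99 feature
#' columns named `<channel>_<feature>` in a fixed, documented order
#' (channels ax, ay, az, gx, gy, gz, a_total, f_exerted, yaw; features min,
#' max, mean, median, sd, variance, kurtosis, rms, skewness, iop, msp).
#'
#' @param subjects List of `subject_dataset` objects (see
#'   [segment_subject()]).
#' @param reference_channel Channel used for within-repetition peak
#'   detection.
#' @param rms_raw Passed to [basic_stats()].
#' @return Data frame; an empty cohort yields a 0-row frame with the full
#'   header.
#' @export
build_feature_matrix <- function(subjects, reference_channel = "gx",
                                 rms_raw = FALSE) {
  meta_cols <- c("subject_id", "hand", "set_index", "rep_index",
                 "effective_rpe", "label")
  fcols <- feature_colnames()
  if (!length(subjects)) {
    empty <- c(
      list(subject_id = character(), hand = character(),
           set_index = integer(), rep_index = integer(),
           effective_rpe = numeric(), label = character()),
      stats::setNames(rep(list(numeric()), length(fcols)), fcols))
    return(as.data.frame(empty, check.names = FALSE))
  }
  featrows <- list()
  meta <- list(subject_id = character(), hand = character(),
               set_index = integer(), rep_index = integer(),
               effective_rpe = numeric(), label = character())
  for (sub in subjects) {
    rep_counter <- 0L
    for (r in sub$repetitions) {
      missing <- setdiff(CHANNEL_NAMES_ALL, names(r$channels))
      if (length(missing)) {
        stop(sprintf(
          "build_feature_matrix(): subject %s repetition %d missing channel(s): %s",
          sub$subject_id, rep_counter + 1L, paste(missing, collapse = ", ")),
          call. = FALSE)
      }
      rep_counter <- rep_counter + 1L
      featrows[[length(featrows) + 1L]] <-
        rep_feature_row(r$channels, r$timestamps,
                        reference_channel = reference_channel,
                        rms_raw = rms_raw)
      meta$subject_id <- c(meta$subject_id, sub$subject_id)
      meta$hand <- c(meta$hand, r$hand)
      meta$set_index <- c(meta$set_index, r$set_index)
      meta$rep_index <- c(meta$rep_index, rep_counter)
      meta$effective_rpe <- c(meta$effective_rpe, r$effective_rpe)
      meta$label <- c(meta$label, r$label)
    }
  }
  featmat <- do.call(rbind, featrows)
  out <- cbind(as.data.frame(meta),
               as.data.frame(featmat, check.names = FALSE))
  rownames(out) <- NULL
  out[, c(meta_cols, fcols)]
}
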