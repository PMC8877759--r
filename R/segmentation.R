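# Repetition segmentation.
#
# One concentration-curl repetition runs trough (full extension) to trough,
# with a single flexion peak in between. Segmentation works on a smoothed
# reference channel (gyroscope x-axis by default): prominence-filtered peak
# detection with a minimum inter-peak distance, then trough cuts between
# consecutive peaks.

#' Segmentation configuration
#'
#' @param reference_channel Channel used for peak detection (default
#'   `"gx"`); the resulting windows are copied verbatim to all channels.
#' @param min_period Minimum repetition period in seconds (default 1).
#' @param prominence_fraction Required peak prominence as a fraction of the
#'   smoothed signal's amplitude range, in (0, 1) (default 0.3).
#' @param smoothing_window Moving-average width in samples (default 5).
#' @return Object of class `segmentation_config`.
#' @export
segmentation_config <- function(reference_channel = "gx", min_period = 1,
                                prominence_fraction = 0.3,
                                smoothing_window = 5L) {
  if (min_period <= 0) {
    stop("segmentation_config(): min_period must be > 0", call. = FALSE)
  }
  if (prominence_fraction <= 0 || prominence_fraction >= 1) {
    stop("segmentation_config(): prominence_fraction must be in (0, 1)",
         call. = FALSE)
  }
  if (smoothing_window < 1) {
    stop("segmentation_config(): smoothing_window must be >= 1",
         call. = FALSE)
  }
  structure(list(reference_channel = reference_channel,
                 min_period = min_period,
                 prominence_fraction = prominence_fraction,
                 smoothing_window = as.integer(smoothing_window)),
            class = "segmentation_config")
}

moving_average <- function(x, width) {
  if (width <= 1L) return(x)
  n <- length(x)
  half <- width %/% 2
  # replicate-pad the ends so the smoothed series keeps full length
  xp <- c(rep(x[1], half), x, rep(x[n], width - half - 1L))
  as.numeric(stats::filter(xp, rep(1 / width, width), sides = 1)[
    seq.int(width, width + n - 1L)])
}

# Topographic prominence of a local maximum: height above the higher of the
# two key saddles (lowest point walked through before reaching higher
# ground, on each side; signal edge counts as higher ground).
peak_prominences <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    lmin <- h
    i <- p - 1L
    while (i >= 1L && x[i] <= h) {
      if (x[i] < lmin) lmin <- x[i]
      i <- i - 1L
    }
    rmin <- h
    i <- p + 1L
    while (i <= length(x) && x[i] <= h) {
      if (x[i] < rmin) rmin <- x[i]
      i <- i + 1L
    }
    h - max(lmin, rmin)
  }, numeric(1))
}

# Local maxima with minimum prominence and minimum spacing. Ties on
# plateaus resolve to the first sample of the plateau. Returns 1-based
# indices, chronological.
find_peaks <- function(x, min_distance = 1L, min_prominence = 0) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  left <- c(Inf, diff(x))
  right <- c(diff(x), -Inf)
  cand <- which(left > 0 & right <= 0)
  cand <- cand[cand > 1L & cand < n]
  if (!length(cand)) return(integer(0))
  prom <- peak_prominences(x, cand)
  cand <- cand[prom >= min_prominence]
  if (!length(cand)) return(integer(0))
  # greedy high-to-low selection enforcing spacing
  ord <- cand[order(x[cand], decreasing = TRUE)]
  keep <- logical(0)
  kept <- integer(0)
  for (p in ord) {
    if (!length(kept) || all(abs(kept - p) >= min_distance)) {
      kept <- c(kept, p)
    }
  }
  sort(kept)
}

#' Segment a set recording into repetition windows
#'
#' Detects flexion peaks on the (smoothed) reference channel and cuts
#' trough-to-trough windows, each containing exactly one peak. Warm-up
#' recordings (`set_index == 0`) are never segmented.
#'
#' @param recording A [set_recording()].
#' @param config A [segmentation_config()].
#' @param sampling A [sampling_spec()] converting `min_period` to samples.
#' @return List of [repetition_window()] (0-based, half-open), chronological;
#'   empty when no peaks are found.
#' @export
segment_repetitions <- function(recording, config = segmentation_config(),
                                sampling = sampling_spec()) {
  if (recording$set_index == 0L) return(list())
  ref <- config$reference_channel
  if (!ref %in% names(recording$channels)) {
    stop(sprintf("segment_repetitions(): reference channel '%s' absent", ref),
         call. = FALSE)
  }
  x <- moving_average(recording$channels[[ref]], config$smoothing_window)
  rng <- diff(range(x))
  if (rng <= 0) return(list())
  peaks <- find_peaks(x,
                      min_distance = max(1L,
                        as.integer(round(config$min_period * sampling$rate))),
                      min_prominence = config$prominence_fraction * rng)
  if (!length(peaks)) return(list())
  # trough between consecutive peaks = argmin of the smoothed signal there
  cuts <- integer(0)
  if (length(peaks) > 1L) {
    cuts <- vapply(seq_len(length(peaks) - 1L), function(i) {
      seg <- peaks[i]:peaks[i + 1L]
      seg[which.min(x[seg])]
    }, integer(1))
  }
  bounds <- c(1L, cuts, length(x) + 1L)  # 1-based starts; last is one-past
  wins <- vector("list", length(peaks))
  for (i in seq_along(peaks)) {
    start0 <- bounds[i] - 1L          # 0-based half-open
    end0 <- bounds[i + 1L] - 1L
    peak0 <- peaks[i] - 1L
    if (peak0 <= start0) peak0 <- start0 + 1L
    if (peak0 >= end0 - 1L) peak0 <- end0 - 2L
    if (end0 - start0 < 3L) next
    wins[[i]] <- repetition_window(start0, end0, peak0)
  }
  wins[!vapply(wins, is.null, TRUE)]
}

#' Copy reference-channel windows onto every channel
#'
#' The same sample indices segment all channels (the IMU is synchronized),
#' so this is pure index bookkeeping.
#'
#' @param windows List of [repetition_window()].
#' @param channels Data frame of channel columns sharing the reference
#'   channel's length.
#' @return List (one element per window) of per-window channel data frames.
#' @export
propagate_windows <- function(windows, channels) {
  if (!length(windows)) return(list())
  n <- nrow(channels)
  lens <- vapply(channels, length, 1L)
  if (any(lens != n)) {
    stop("propagate_windows(): channel lengths differ", call. = FALSE)
  }
  maxend <- max(vapply(windows, function(w) w$end, 1L))
  if (maxend > n) {
    stop("propagate_windows(): window exceeds channel length", call. = FALSE)
  }
  lapply(windows, function(w) {
    channels[(w$start + 1L):w$end, , drop = FALSE]
  })
}

#' Fatigue labels for a set's repetitions
#'
#' All repetitions of a set share the set's label: `fatigue` iff the
#' effective RPE is strictly greater than 16, else `non_fatigue`.
#'
#' @param windows List of [repetition_window()].
#' @param effective_rpe Effective Borg value in `[6, 20]`.
#' @return Character vector of labels, one per window.
#' @export
label_repetitions <- function(windows, effective_rpe) {
  if (effective_rpe < 6 || effective_rpe > 20) {
    stop("label_repetitions(): effective_rpe must be in [6, 20]",
         call. = FALSE)
  }
  rep(if (effective_rpe > 16) "fatigue" else "non_fatigue", length(windows))
}

#' Segment and label every repetition of one subject
#'
#' Runs derivation, segmentation, RPE reconciliation and labeling over all
#' non-warm-up recordings of a subject, in (hand, set_index) order.
#'
#' @param subject Subject entry (`subject_id`, `traits`, `recordings`).
#' @param config A [segmentation_config()].
#' @param sampling A [sampling_spec()].
#' @param mass Dumbbell mass (kg) for the force channel.
#' @param rpe_tolerance Tolerance for [reconcile_rpe()].
#' @return A `subject_dataset`: list with `subject_id`, `traits` and
#'   `repetitions` (each carrying the nine-channel slice, timestamps,
#'   window, `hand`, `set_index`, `effective_rpe`, `label`).
#' @export
segment_subject <- function(subject, config = segmentation_config(),
                            sampling = sampling_spec(), mass = 4.5,
                            rpe_tolerance = 2) {
  recs <- subject$recordings
  ord <- order(vapply(recs, function(r) r$hand, ""),
               vapply(recs, function(r) r$set_index, 1L))
  reps <- list()
  for (rec in recs[ord]) {
    if (rec$set_index == 0L) next
    wins <- segment_repetitions(rec, config, sampling)
    if (!length(wins)) next
    ch9 <- derive_channels(rec, mass = mass, sampling = sampling)
    slices <- propagate_windows(wins, ch9)
    erpe <- reconcile_rpe(rec$reported_rpe, rec$heart_rate, rpe_tolerance)
    labels <- label_repetitions(wins, erpe)
    for (i in seq_along(wins)) {
      w <- wins[[i]]
      reps[[length(reps) + 1L]] <- list(
        window = w, channels = slices[[i]],
        timestamps = rec$timestamps[(w$start + 1L):w$end],
        hand = rec$hand, set_index = rec$set_index,
        effective_rpe = erpe, label = labels[i])
    }
  }
  structure(list(subject_id = subject$subject_id, traits = subject$traits,
                 repetitions = reps),
            class = "subject_dataset")
}
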