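#' Body mass index from weight and height
#'
#' BMI = weight (kg) / height (m)^2, with height supplied in centimetres as
#' recorded on the trait sheets.
#'
#' @param weight Body weight in kg. Must be strictly positive.
#' @param height Standing height in cm. Must be strictly positive.
#' @return BMI in kg/m^2. Vectorised over both arguments.
#' @examples
#' compute_bmi(100, 200) # 25
#' @export
compute_bmi <- function(weight, height) {
  if (!is.numeric(weight) || !is.numeric(height)) {
    stop("compute_bmi(): weight and height must be numeric", call. = FALSE)
  }
  if (any(weight <= 0) || any(height <= 0)) {
    stop("compute_bmi(): weight and height must be strictly positive",
         call. = FALSE)
  }
  weight / (height / 100)^2
}

#' Physical trait vector for one subject
#'
#' The four traits used by the physical-similarity score: age, height,
#' weight and BMI. When `bmi` is omitted it is derived from weight and
#' height.
#'
#' @param age Age in years.
#' @param height Height in cm.
#' @param weight Weight in kg.
#' @param bmi Optional BMI in kg/m^2; computed from `weight`/`height` when
#'   `NULL`.
#' @return An object of class `physical_traits` (a named list).
#' @export
physical_traits <- function(age, height, weight, bmi = NULL) {
  vals <- c(age = age, height = height, weight = weight)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("physical_traits(): age, height and weight must be finite and > 0",
         call. = FALSE)
  }
  if (is.null(bmi)) bmi <- compute_bmi(weight, height)
  if (!is.finite(bmi) || bmi <= 0) {
    stop("physical_traits(): bmi must be finite and > 0", call. = FALSE)
  }
  structure(list(age = age, height = height, weight = weight, bmi = bmi),
            class = "physical_traits")
}

#' @export
as.numeric.physical_traits <- function(x, ...) {
  c(age = x$age, height = x$height, weight = x$weight, bmi = x$bmi)
}

#' Sampling specification
#'
#' @param rate Sampling rate in Hz (default 50, the wrist IMU's rate).
#' @return Object of class `sampling_spec` with fields `rate` and `dt`.
#' @export
sampling_spec <- function(rate = 50) {
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("sampling_spec(): rate must be a single positive number",
         call. = FALSE)
  }
  structure(list(rate = rate, dt = 1 / rate), class = "sampling_spec")
}

CHANNEL_NAMES_RAW <- c("ax", "ay", "az", "gx", "gy", "gz")
CHANNEL_NAMES_ALL <- c(CHANNEL_NAMES_RAW, "a_total", "f_exerted", "yaw")
HAND_LEVELS <- c("left", "right")

#' One exercise set's IMU recording
#'
#' Bundles the six raw channels of a single set (or warm-up) with its
#' set-level Borg RPE report and heart-rate reading. Accelerometer channels
#' are in m/s^2, gyroscope channels in deg/s.
#'
#' @param subject_id Opaque subject label.
#' @param hand `"left"` or `"right"`.
#' @param set_index Integer 0..5; 0 marks the warm-up set.
#' @param timestamps Strictly increasing sample times in seconds.
#' @param channels Data frame with columns `ax, ay, az, gx, gy, gz`, all the
#'   same length as `timestamps` (>= 2 samples).
#' @param reported_rpe Borg rating reported for the set, in `[6, 20]`.
#' @param heart_rate Heart rate during the set, bpm.
#' @return Object of class `set_recording`.
#' @export
set_recording <- function(subject_id, hand, set_index, timestamps, channels,
                          reported_rpe, heart_rate) {
  hand <- match.arg(hand, HAND_LEVELS)
  if (!set_index %in% 0:5) {
    stop("set_recording(): set_index must be in 0..5", call. = FALSE)
  }
  if (!is.data.frame(channels) ||
      !all(CHANNEL_NAMES_RAW %in% names(channels))) {
    missing <- setdiff(CHANNEL_NAMES_RAW, names(channels))
    stop(sprintf("set_recording(): missing channel column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  channels <- channels[CHANNEL_NAMES_RAW]
  n <- length(timestamps)
  if (n < 2L) stop("set_recording(): need >= 2 samples", call. = FALSE)
  if (any(vapply(channels, length, 1L) != n)) {
    stop("set_recording(): all six channels must match timestamp length",
         call. = FALSE)
  }
  if (any(diff(timestamps) <= 0)) {
    stop("set_recording(): timestamps must be strictly increasing",
         call. = FALSE)
  }
  if (reported_rpe < 6 || reported_rpe > 20) {
    stop("set_recording(): reported_rpe must be in [6, 20]", call. = FALSE)
  }
  if (heart_rate <= 0) {
    stop("set_recording(): heart_rate must be positive", call. = FALSE)
  }
  structure(
    list(subject_id = as.character(subject_id), hand = hand,
         set_index = as.integer(set_index),
         timestamps = as.numeric(timestamps),
         channels = as.data.frame(channels),
         reported_rpe = as.numeric(reported_rpe),
         heart_rate = as.numeric(heart_rate)),
    class = "set_recording"
  )
}

#' One segmented repetition window
#'
#' Indices are 0-based and the window is half-open `[start, end)`; `peak` is
#' the sample index of full flexion. Used uniformly across the package.
#'
#' @param start,end 0-based half-open window bounds.
#' @param peak 0-based index of the flexion peak, `start < peak < end`.
#' @return Object of class `repetition_window`.
#' @export
repetition_window <- function(start, end, peak) {
  if (!(start < peak && peak < end)) {
    stop("repetition_window(): need start < peak < end", call. = FALSE)
  }
  if (end - start < 3L) {
    stop("repetition_window(): window must span >= 3 samples", call. = FALSE)
  }
  structure(list(start = as.integer(start), end = as.integer(end),
                 peak = as.integer(peak)),
            class = "repetition_window")
}

window_length <- function(w) w$end - w$start
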