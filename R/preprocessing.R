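# Derived channels and RPE handling.
#
# The Borg scale times ten approximates heart rate (Borg 13 ~ 130-140 bpm),
# which is used to sanity-check the self-reported exertion: when the two
# disagree by more than a tolerance, the effective RPE is the average of the
# report and heart_rate/10.

#' Reconcile reported Borg RPE with measured heart rate
#'
#' If `|heart_rate/10 - reported_rpe| <= tolerance` the report stands;
#' otherwise the effective RPE is the mean of the report and
#' `heart_rate/10`, clipped to the Borg range `[6, 20]`.
#'
#' @param reported_rpe Borg rating in `[6, 20]`.
#' @param heart_rate Heart rate in bpm (> 0).
#' @param tolerance Disagreement tolerance in Borg units (default 2).
#' @return Effective RPE on the Borg scale (possibly fractional).
#' @export
reconcile_rpe <- function(reported_rpe, heart_rate, tolerance = 2) {
  if (any(reported_rpe < 6 | reported_rpe > 20)) {
    stop("reconcile_rpe(): reported_rpe must be in [6, 20]", call. = FALSE)
  }
  if (any(heart_rate <= 0)) {
    stop("reconcile_rpe(): heart_rate must be positive", call. = FALSE)
  }
  hr_rpe <- heart_rate / 10
  out <- ifelse(abs(hr_rpe - reported_rpe) <= tolerance,
                reported_rpe, (reported_rpe + hr_rpe) / 2)
  pmin(pmax(out, 6), 20)
}

#' Total acceleration magnitude
#'
#' Pointwise `sqrt(ax^2 + ay^2 + az^2)` -- placement-independent since it is
#' invariant to any signed permutation of the axes.
#'
#' @param ax,ay,az Accelerometer series in m/s^2, equal lengths.
#' @return Series in m/s^2.
#' @export
total_acceleration <- function(ax, ay, az) {
  n <- length(ax)
  if (length(ay) != n || length(az) != n) {
    stop("total_acceleration(): channel lengths differ", call. = FALSE)
  }
  sqrt(ax^2 + ay^2 + az^2)
}

#' Exerted force to lift the dumbbell
#'
#' `F = m * a` applied literally with the dumbbell mass (default 4.5 kg, the
#' protocol's dumbbell); no gravity compensation.
#'
#' @param a_total Total-acceleration series, m/s^2.
#' @param mass Dumbbell mass in kg (> 0).
#' @return Force series in N.
#' @export
exerted_force <- function(a_total, mass = 4.5) {
  if (!is.numeric(mass) || length(mass) != 1L || mass <= 0) {
    stop("exerted_force(): mass must be a single positive number",
         call. = FALSE)
  }
  mass * a_total
}

#' Complementary-filter fusion of gyroscope rate and accelerometer angle
#'
#' First-order recurrence `angle <- 0.98 * (angle + gyro * dt) + 0.02 * acc`
#' applied left-to-right from `initial_angle`. The gyroscope term tracks
#' fast motion; the accelerometer term pins the slow drift.
#'
#' @param gyro_rate Angular rate series, deg/s.
#' @param acc_angle Accelerometer-derived angle series, deg.
#' @param dt Sample period in seconds (> 0).
#' @param initial_angle Starting angle in deg (default 0).
#' @param k_gyro Gyroscope weight (default 0.98); the accelerometer weight
#'   is `1 - k_gyro`.
#' @return Fused angle series, same length as the inputs.
#' @export
fuse_acc_gyro <- function(gyro_rate, acc_angle, dt, initial_angle = 0,
                          k_gyro = 0.98) {
  n <- length(gyro_rate)
  if (length(acc_angle) != n) {
    stop("fuse_acc_gyro(): input lengths differ", call. = FALSE)
  }
  if (dt <= 0) stop("fuse_acc_gyro(): dt must be positive", call. = FALSE)
  if (k_gyro < 0 || k_gyro > 1) {
    stop("fuse_acc_gyro(): k_gyro must lie in [0, 1]", call. = FALSE)
  }
  if (n == 0L) return(numeric(0))
  # angle_i = k * angle_{i-1} + (k * gyro_i * dt + (1-k) * acc_i)
  drive <- k_gyro * gyro_rate * dt + (1 - k_gyro) * acc_angle
  as.numeric(stats::filter(drive, k_gyro, method = "recursive",
                           init = initial_angle))
}

# Accelerometer-derived angle feeding the fusion filter: atan2(ay, ax) in
# degrees, unwrapped so the recurrence sees a continuous series. The IMU
# cannot observe yaw from gravity alone; this planar convention is the
# package's documented stand-in.
acc_plane_angle <- function(ax, ay) {
  ang <- atan2(ay, ax)
  unwrap_radians(ang) * 180 / pi
}

unwrap_radians <- function(x) {
  if (length(x) < 2L) return(x)
  d <- diff(x)
  jumps <- round(d / (2 * pi))
  x - c(0, cumsum(jumps)) * 2 * pi
}

#' Attach the three derived channels to a set recording
#'
#' Returns the nine-channel frame used by feature extraction: the six raw
#' channels plus `a_total`, `f_exerted` and the complementary-filter `yaw`.
#'
#' @param recording A [set_recording()].
#' @param mass Dumbbell mass in kg for the force channel.
#' @param sampling A [sampling_spec()] supplying `dt` for the fusion filter.
#' @return Data frame with the nine channel columns.
#' @export
derive_channels <- function(recording, mass = 4.5,
                            sampling = sampling_spec()) {
  ch <- recording$channels
  a_tot <- total_acceleration(ch$ax, ch$ay, ch$az)
  acc_ang <- acc_plane_angle(ch$ax, ch$ay)
  yaw <- fuse_acc_gyro(ch$gx, acc_ang, dt = sampling$dt)
  cbind(ch,
        data.frame(a_total = a_tot,
                   f_exerted = exerted_force(a_tot, mass),
                   yaw = yaw))
}
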