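# Seeded synthetic cohort generator.
#
# The generator states the world the pipeline assumes rather than
# simulating biomechanics: each subject belongs to a movement-style
# cluster (correlated with age/BMI at a configurable coupling), produces
# quasi-sinusoidal curl cycles on the gyroscope x-axis, and fatigues across
# sets through exactly the signatures the features measure -- longer cycle
# periods (IoP), decaying peak amplitudes (MSP) and increasingly
# positive-skewed cycles. RPE rises across sets and crosses the fatigue
# threshold (16) in the last two sets; heart rate tracks 10 x RPE.

#' Synthetic cohort configuration
#'
#' Defaults restate the data-collection protocol: 25 subjects, 5 warm-up
#' reps plus 5 sets x 15 reps per hand at 50 Hz, trait ranges age 20-46 y /
#' weight 69-127 kg / height 165-190 cm with BMI kept in 24-46 by
#' rejection, and a per-set Borg trajectory 9, 11, 13, 15, 17, 19
#' (warm-up + 5 sets) that crosses 16 between sets 4 and 5.
#'
#' @param n_subjects Number of subjects (default 25).
#' @param sets_per_hand Work sets per hand (default 5).
#' @param reps_per_set Repetitions per work set (default 15).
#' @param warmup_reps Warm-up repetitions (default 5, set_index 0).
#' @param sampling A [sampling_spec()] (default 50 Hz).
#' @param age_range,weight_range,height_range,bmi_range Trait ranges.
#' @param n_style_clusters Movement-style clusters (default 3).
#' @param trait_style_coupling Coupling strength in `[0, 1]` (default 1):
#'   the style position blends the trait-determined coordinate with a
#'   uniform draw at this weight, and the cluster equals the deterministic
#'   (age, BMI) region with this probability (uniform otherwise).
#' @param noise_sd Additive Gaussian noise on the reference gyroscope
#'   channel, deg/s (default 4, roughly 5-10% of cycle amplitude).
#' @param rpe_trajectory Base Borg value per set (warm-up first),
#'   non-decreasing with final value > 16.
#' @param seed RNG seed (default 1).
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 25L, sets_per_hand = 5L,
                          reps_per_set = 15L, warmup_reps = 5L,
                          sampling = sampling_spec(50),
                          age_range = c(20, 46), weight_range = c(69, 127),
                          height_range = c(165, 190), bmi_range = c(24, 46),
                          n_style_clusters = 3L, trait_style_coupling = 1,
                          noise_sd = 4,
                          rpe_trajectory = c(9, 11, 13, 15, 17, 19),
                          seed = 1L) {
  if (length(rpe_trajectory) != sets_per_hand + 1L) {
    stop("cohort_config(): rpe_trajectory needs one value per set incl. warm-up",
         call. = FALSE)
  }
  if (is.unsorted(rpe_trajectory)) {
    stop("cohort_config(): rpe_trajectory must be non-decreasing",
         call. = FALSE)
  }
  if (rpe_trajectory[length(rpe_trajectory)] <= 16) {
    stop("cohort_config(): final-set base RPE must exceed 16", call. = FALSE)
  }
  if (trait_style_coupling < 0 || trait_style_coupling > 1) {
    stop("cohort_config(): trait_style_coupling must lie in [0, 1]",
         call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 sets_per_hand = as.integer(sets_per_hand),
                 reps_per_set = as.integer(reps_per_set),
                 warmup_reps = as.integer(warmup_reps), sampling = sampling,
                 age_range = age_range, weight_range = weight_range,
                 height_range = height_range, bmi_range = bmi_range,
                 n_style_clusters = as.integer(n_style_clusters),
                 trait_style_coupling = trait_style_coupling,
                 noise_sd = noise_sd, rpe_trajectory = rpe_trajectory,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Movement style as a function of a position (z1, z2) in [0, 1]^2 on the
# trait plane: z1 (age/BMI) drives tempo and pulse shape, z2
# (height/weight) drives amplitude and cross-axis geometry. Both vary
# continuously, so subjects with nearby traits move alike while the cohort
# spreads over a 2-D style plane that 25 subjects only cover sparsely --
# absolute feature values alone do not identify fatigue. Style clusters
# are coarse regions of the z1 axis, and each expresses one DOMINANT
# fatigue signature (slowing, amplitude loss, or skew) with the others
# nearly silent, so no single feature separates fatigue globally: that
# subject-conditional mapping is the inter-subject variability the
# personalization exists to mitigate.
# Units: seconds, deg/s, fractions per set.
style_from_position <- function(z1, z2, cluster) {
  lerp <- function(z, lo, hi) lo + z * (hi - lo)
  dominant <- (cluster - 1L) %% 3L + 1L
  list(base_period = lerp(z1, 1.7, 2.5),
       pulse_shape = lerp(z1, 1.8, 2.4),
       ripple_n = lerp(z1, 5, 8),
       amplitude = lerp(z2, 50, 100),
       lag_frac = lerp(z2, 0.06, 0.14),
       gy_gain = lerp(z2, 0.35, 0.55),
       gz_gain = lerp(z2, 0.20, 0.40),
       fatigue_period_growth = c(0.10, 0.015, 0.025)[dominant],
       fatigue_amplitude_decay = c(0.015, 0.10, 0.025)[dominant],
       fatigue_skew_gain = c(0.06, 0.06, 0.55)[dominant])
}

#' Draw one synthetic subject
#'
#' Traits are uniform within their ranges, rejected until BMI lands in the
#' configured band. With coupling `c` the style cluster equals the
#' deterministic (age, BMI) region with probability `c` and is uniform
#' otherwise; continuous style parameters come from the trait-plane
#' position (blended with a uniform draw at weight `1 - c`) with small
#' multiplicative jitter.
#'
#' @param config A [cohort_config()]. Uses the current RNG state.
#' @return List with `traits`, `cluster` and `style`.
#' @export
sample_subject <- function(config) {
  for (i in seq_len(10000L)) {
    age <- stats::runif(1, config$age_range[1], config$age_range[2])
    height <- stats::runif(1, config$height_range[1], config$height_range[2])
    weight <- stats::runif(1, config$weight_range[1], config$weight_range[2])
    bmi <- compute_bmi(weight, height)
    if (bmi >= config$bmi_range[1] && bmi <= config$bmi_range[2]) break
    if (i == 10000L) {
      stop("sample_subject(): infeasible trait ranges (BMI rejection failed)",
           call. = FALSE)
    }
  }
  traits <- physical_traits(age, height, weight)
  k <- config$n_style_clusters
  cpl <- config$trait_style_coupling
  z_age <- (age - config$age_range[1]) / diff(config$age_range)
  z_bmi <- (bmi - config$bmi_range[1]) / diff(config$bmi_range)
  z_hgt <- (height - config$height_range[1]) / diff(config$height_range)
  z_wgt <- (weight - config$weight_range[1]) / diff(config$weight_range)
  # two trait-plane coordinates: a small Manhattan distance over the four
  # normalized traits guarantees both are nearby, so the physical
  # similarity the pipeline computes is an honest style proxy
  z1t <- (z_age + z_bmi) / 2
  z2t <- (z_age + z_bmi + z_hgt + z_wgt) / 4
  # style position: trait-determined at coupling 1, uniform at coupling 0
  z1 <- cpl * z1t + (1 - cpl) * stats::runif(1)
  z2 <- cpl * z2t + (1 - cpl) * stats::runif(1)
  region <- function(z) min(floor(z * k) + 1L, k)
  cluster <- if (stats::runif(1) < cpl) region(z1t) else sample.int(k, 1L)
  base <- style_from_position(z1, z2, cluster)
  # small multiplicative jitter on baselines; per-subject channel gains and
  # phase lag add fatigue-irrelevant idiosyncrasy
  style <- list(
    base_period = base$base_period * stats::runif(1, 0.97, 1.03),
    amplitude = base$amplitude * stats::runif(1, 0.95, 1.05),
    pulse_shape = base$pulse_shape * stats::runif(1, 0.97, 1.03),
    fatigue_period_growth =
      base$fatigue_period_growth * stats::runif(1, 0.8, 1.2),
    fatigue_amplitude_decay =
      base$fatigue_amplitude_decay * stats::runif(1, 0.8, 1.2),
    fatigue_skew_gain = base$fatigue_skew_gain * stats::runif(1, 0.8, 1.2),
    lag_frac = base$lag_frac * stats::runif(1, 0.95, 1.05),
    ripple_n = base$ripple_n * stats::runif(1, 0.97, 1.03),
    gy_gain = base$gy_gain * stats::runif(1, 0.95, 1.05),
    gz_gain = base$gz_gain * stats::runif(1, 0.95, 1.05))
  list(traits = traits, cluster = cluster, style = style)
}

# One curl cycle sampled on n points: a sin^q pulse with a small tremor
# ripple. q = 2 gives a symmetric (zero-skew) cycle; larger q narrows the
# peak, which makes the sampled values positively skewed -- the fatigue
# signature. The ripple (ripple_n bumps per cycle, enveloped so it
# vanishes at the troughs) gives every repetition internal sub-movement
# peaks whose spacing scales with the cycle period, so the interval-of-
# peaks feature genuinely measures movement slowing.
curl_cycle <- function(n, amplitude, q, ripple_n = 6, ripple_amp = 0.1) {
  u <- (seq_len(n) - 1) / n
  env <- sin(pi * u)
  amplitude * (env^q + ripple_amp * sin(2 * pi * ripple_n * u) * env)
}

#' Generate one set's recording for a subject
#'
#' Builds `reps_per_set` (or `warmup_reps` for set 0) quasi-sinusoidal
#' cycles on the gyroscope x-axis with the subject's style fatigued by
#' `set_index` (period grows, amplitude decays, skew rises), derives the
#' remaining channels as phase-lagged, attenuated copies plus noise, and
#' attaches an RPE report (trajectory value with +/-1 jitter) and a heart
#' rate of `10 * RPE + N(0, 5)`.
#'
#' @param subject_id Subject label.
#' @param style Style list from [sample_subject()].
#' @param hand `"left"` or `"right"`.
#' @param set_index 0 (warm-up) .. `sets_per_hand`.
#' @param config A [cohort_config()]. Uses the current RNG state.
#' @return A [set_recording()].
#' @export
generate_set_signal <- function(subject_id, style, hand, set_index, config) {
  n_reps <- if (set_index == 0L) config$warmup_reps else config$reps_per_set
  rate <- config$sampling$rate
  period <- style$base_period * (1 + style$fatigue_period_growth)^set_index
  amp <- style$amplitude * (1 - style$fatigue_amplitude_decay)^set_index
  q <- (style$pulse_shape %||% 2) + style$fatigue_skew_gain * set_index
  clean <- unlist(lapply(seq_len(n_reps), function(r) {
    n <- max(3L, as.integer(round(period * stats::runif(1, 0.97, 1.03) * rate)))
    curl_cycle(n, amp, q, ripple_n = style$ripple_n %||% 6)
  }))
  n <- length(clean)
  lag_k <- max(1L, as.integer(round((style$lag_frac %||% 0.1) * period * rate)))
  lagged <- function(x, k) c(rep(x[1], k), x[seq_len(length(x) - k)])
  nsd <- config$noise_sd
  acc_scale <- amp / 12          # gyro deg/s -> accelerometer m/s^2 scale
  acc_nsd <- nsd / 12
  pulse_unit <- clean / max(amp, .Machine$double.eps)   # 0..1 shape
  channels <- data.frame(
    ax = 0.50 * acc_scale * pulse_unit + stats::rnorm(n, 0, acc_nsd),
    ay = 0.35 * acc_scale * lagged(pulse_unit, lag_k) +
      stats::rnorm(n, 0, acc_nsd),
    az = 9.81 - 0.25 * acc_scale * pulse_unit + stats::rnorm(n, 0, acc_nsd),
    gx = clean + stats::rnorm(n, 0, nsd),
    gy = (style$gy_gain %||% 0.45) * lagged(clean, lag_k) +
      stats::rnorm(n, 0, nsd),
    gz = (style$gz_gain %||% 0.30) * lagged(clean, 2L * lag_k) +
      stats::rnorm(n, 0, 0.8 * nsd))
  rpe <- config$rpe_trajectory[set_index + 1L] + sample(-1:1, 1L)
  rpe <- min(max(rpe, 6), 20)
  hr <- 10 * rpe + stats::rnorm(1, 0, 5)
  set_recording(subject_id = subject_id, hand = hand, set_index = set_index,
                timestamps = (seq_len(n) - 1) * config$sampling$dt,
                channels = channels, reported_rpe = rpe,
                heart_rate = max(hr, 1))
}

#' Generate a full synthetic cohort
#'
#' Deterministic given `config$seed`: n_subjects subjects, each with 2
#' hands x (1 warm-up + `sets_per_hand` work sets). The ground-truth
#' manifest records traits, cluster and style per subject; fatigue labels
#' are never stored -- they always derive from the generated RPE through
#' the > 16 rule downstream.
#'
#' @param config A [cohort_config()].
#' @return List with `cohort` (an [imu_cohort()]) and `manifest`
#'   (data frame of per-subject ground truth).
#' @export
generate_cohort <- function(config = cohort_config()) {
  with_seed(config$seed, {
    subjects <- vector("list", config$n_subjects)
    man <- list()
    for (s in seq_len(config$n_subjects)) {
      sid <- sprintf("S%02d", s)
      drawn <- sample_subject(config)
      recs <- list()
      for (hand in HAND_LEVELS) {
        for (set_index in 0:config$sets_per_hand) {
          recs[[length(recs) + 1L]] <-
            generate_set_signal(sid, drawn$style, hand, set_index, config)
        }
      }
      subjects[[s]] <- list(subject_id = sid, traits = drawn$traits,
                            recordings = recs)
      man[[s]] <- data.frame(
        subject_id = sid, cluster = drawn$cluster,
        age = drawn$traits$age, height = drawn$traits$height,
        weight = drawn$traits$weight, bmi = drawn$traits$bmi,
        base_period = drawn$style$base_period,
        amplitude = drawn$style$amplitude,
        pulse_shape = drawn$style$pulse_shape,
        ripple_n = drawn$style$ripple_n,
        fatigue_period_growth = drawn$style$fatigue_period_growth,
        fatigue_amplitude_decay = drawn$style$fatigue_amplitude_decay,
        fatigue_skew_gain = drawn$style$fatigue_skew_gain)
    }
    list(cohort = imu_cohort(subjects), manifest = do.call(rbind, man))
  })
}

#' Segment, label and featurize a cohort
#'
#' Convenience wrapper running [segment_subject()] and
#' [build_feature_matrix()] over every subject.
#'
#' @param cohort An [imu_cohort()].
#' @param config A [segmentation_config()].
#' @param sampling A [sampling_spec()].
#' @param mass Dumbbell mass (kg).
#' @param rpe_tolerance Tolerance for [reconcile_rpe()].
#' @return List with `features` (feature table) and `traits` (named list of
#'   [physical_traits()] keyed by subject id).
#' @export
cohort_features <- function(cohort, config = segmentation_config(),
                            sampling = sampling_spec(), mass = 4.5,
                            rpe_tolerance = 2) {
  datasets <- lapply(cohort$subjects, segment_subject, config = config,
                     sampling = sampling, mass = mass,
                     rpe_tolerance = rpe_tolerance)
  traits <- lapply(cohort$subjects, function(s) s$traits)
  names(traits) <- names(cohort$subjects)
  list(features = build_feature_matrix(datasets), traits = traits)
}
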