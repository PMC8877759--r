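# Shared fixtures. Small cohorts keep unit tests fast; the default-size
# cohort (25 subjects, 50 Hz) is built lazily once and reused by the
# acceptance tests.

make_sine_recording <- function(period = 2, duration = 30, rate = 50,
                                amplitude = 50, noise_sd = 0, phase = 0,
                                rpe = 13, hr = 130, set_index = 1L,
                                seed = 42L) {
  n <- as.integer(duration * rate)
  t <- (seq_len(n) - 1) / rate
  x <- amplitude * (1 - cos(2 * pi * (t + phase) / period)) / 2
  if (noise_sd > 0) {
    x <- x + withr::with_seed(seed, rnorm(n, 0, noise_sd))
  }
  ch <- data.frame(ax = 0.3 * x / 10, ay = 0.2 * x / 10, az = 9.81 + 0 * x,
                   gx = x, gy = 0.5 * x, gz = 0.25 * x)
  set_recording("T01", "left", set_index, t, ch, rpe, hr)
}

small_cohort_config <- function(seed = 1L, n_subjects = 6L) {
  cohort_config(n_subjects = n_subjects, reps_per_set = 6L,
                warmup_reps = 2L, seed = seed)
}

# cached per-seed default cohorts with features (shared across test files)
.cohort_cache <- new.env(parent = emptyenv())
default_cohort_features <- function(seed) {
  key <- as.character(seed)
  if (is.null(.cohort_cache[[key]])) {
    gen <- generate_cohort(cohort_config(seed = seed))
    cf <- cohort_features(gen$cohort)
    .cohort_cache[[key]] <- list(gen = gen, features = cf$features,
                                 traits = cf$traits)
  }
  .cohort_cache[[key]]
}

# brute-force population statistics used as the independent oracle
oracle_stats <- function(x) {
  n <- length(x)
  m <- 0
  for (v in x) m <- m + v / n
  s2 <- 0
  for (v in x) s2 <- s2 + (v - m)^2 / n
  s <- sqrt(s2)
  sk <- ku <- 0
  if (s > 0) {
    for (v in x) {
      sk <- sk + (v - m)^3 / n
      ku <- ku + (v - m)^4 / n
    }
    sk <- sk / s^3
    ku <- ku / s^4
  }
  c(min = min(x), max = max(x), mean = m, median = median(x), sd = s,
    variance = s2, kurtosis = ku, rms = s, skewness = sk)
}
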