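test_that("basic_stats matches hand-computed population values", {
  s <- basic_stats(c(1, 2, 3, 4))
  expect_equal(s[["mean"]], 2.5)
  expect_equal(s[["median"]], 2.5)
  expect_equal(s[["variance"]], 1.25)
  expect_equal(s[["sd"]], sqrt(1.25))
  expect_equal(s[["skewness"]], 0)
  # symmetric series: skewness exactly 0; kurtosis 1.7 by brute force
  s2 <- basic_stats(c(-2, -1, 0, 1, 2))
  expect_equal(s2[["skewness"]], 0)
  expect_equal(s2[["kurtosis"]], 1.7)
  # degenerate constant series convention
  s3 <- basic_stats(c(5, 5, 5))
  expect_equal(unname(s3[c("min", "max", "mean", "median")]), rep(5, 4))
  expect_equal(unname(s3[c("sd", "variance", "rms", "skewness",
                           "kurtosis")]), rep(0, 5))
  expect_error(basic_stats(numeric(0)), "empty")
})

test_that("basic_stats agrees with the brute-force oracle on random series", {
  withr::with_seed(101, {
    for (i in 1:1000) {
      n <- sample(3:500, 1)
      x <- switch(1 + i %% 3,
                  rnorm(n, sd = runif(1, 0.1, 50)),
                  rexp(n, rate = runif(1, 0.1, 5)),
                  runif(n, -10, 10))
      expect_equal(basic_stats(x), oracle_stats(x), tolerance = 1e-9)
    }
  })
})

test_that("basic_stats is affine-equivariant", {
  withr::with_seed(7, {
    for (i in 1:25) {
      x <- rnorm(60, sd = 3)
      a <- runif(1, 0.1, 5)
      b <- runif(1, -10, 10)
      s <- basic_stats(x)
      sy <- basic_stats(a * x + b)
      for (nm in c("min", "max", "mean", "median")) {
        expect_equal(sy[[nm]], a * s[[nm]] + b, tolerance = 1e-9)
      }
      expect_equal(sy[["sd"]], a * s[["sd"]], tolerance = 1e-9)
      expect_equal(sy[["rms"]], a * s[["rms"]], tolerance = 1e-9)
      expect_equal(sy[["variance"]], a^2 * s[["variance"]],
                   tolerance = 1e-9)
      expect_equal(sy[["skewness"]], s[["skewness"]], tolerance = 1e-9)
      expect_equal(sy[["kurtosis"]], s[["kurtosis"]], tolerance = 1e-9)
    }
  })
})

test_that("rms equals sd as printed, or the raw form behind the switch", {
  x <- rnorm(50, mean = 3)
  expect_equal(basic_stats(x)[["rms"]], basic_stats(x)[["sd"]])
  expect_equal(basic_stats(x, rms_raw = TRUE)[["rms"]],
               sqrt(mean(x^2)))
})

test_that("detect_peaks_in_rep honors its contract", {
  t <- (0:49) / 50
  hump <- sin(pi * t / max(t))
  p <- detect_peaks_in_rep(hump, t)
  expect_length(p$times, 1)
  expect_equal(p$indices, which.max(hump))
  # two equal humps, chronological
  x2 <- c(hump, 0, hump)
  t2 <- (seq_along(x2) - 1) / 50
  p2 <- detect_peaks_in_rep(x2, t2)
  expect_length(p2$times, 2)
  expect_true(all(diff(p2$times) > 0))
  # monotone ramp: single peak at the last sample
  ramp <- seq(0, 1, length.out = 30)
  tr <- (0:29) / 50
  pr <- detect_peaks_in_rep(ramp, tr)
  expect_equal(pr$indices, 30L)
  expect_error(detect_peaks_in_rep(1:2, c(0, 1)), ">= 3")
})

test_that("interval_of_peaks averages successive gaps", {
  ps <- structure(list(times = c(1, 3, 5, 7), amplitudes = rep(1, 4)),
                  class = "peak_set")
  expect_equal(interval_of_peaks(ps), 2)
  ps2 <- structure(list(times = c(0, 1, 3), amplitudes = rep(1, 3)),
                   class = "peak_set")
  expect_equal(interval_of_peaks(ps2), 1.5)
  single <- structure(list(times = 2, amplitudes = 1), class = "peak_set")
  expect_equal(interval_of_peaks(single), 0)
})

test_that("IoP recovers the hump period on evenly spaced humps", {
  rate <- 50
  for (k in c(4, 7, 10)) {
    for (T in c(0.4, 0.8)) {
      n <- round(T * rate)
      x <- rep(sin(pi * (seq_len(n) - 1) / n), k)
      t <- (seq_along(x) - 1) / rate
      p <- detect_peaks_in_rep(x, t, smoothing_window = 1,
                               prominence_fraction = 0.2)
      expect_equal(interval_of_peaks(p), T, tolerance = 1 / rate)
    }
  }
})

test_that("mean_slope_peaks matches pair enumeration and its symmetries", {
  ps <- structure(list(times = c(0, 1), amplitudes = c(1, 3)),
                  class = "peak_set")
  expect_equal(mean_slope_peaks(ps), 1) # (2 + 2) / 4
  flat <- structure(list(times = c(0, 2, 5), amplitudes = c(2, 2, 2)),
                    class = "peak_set")
  expect_equal(mean_slope_peaks(flat), 0)
  # brute-force oracle on random peak sets; reversal negates MSP
  withr::with_seed(33, {
    for (i in 1:50) {
      np <- sample(2:8, 1)
      # a symmetric time grid: amplitude reversal then exactly negates MSP
      times <- seq(0, by = runif(1, 0.5, 2), length.out = np)
      amps <- rnorm(np)
      ps <- structure(list(times = times, amplitudes = amps),
                      class = "peak_set")
      brute <- 0
      for (a in seq_len(np)) {
        for (b in seq_len(np)) {
          if (a != b) {
            brute <- brute + (amps[b] - amps[a]) / (times[b] - times[a])
          }
        }
      }
      expect_equal(mean_slope_peaks(ps), brute / np^2, tolerance = 1e-9)
      rev_ps <- structure(list(times = times, amplitudes = rev(amps)),
                          class = "peak_set")
      expect_equal(mean_slope_peaks(rev_ps), -mean_slope_peaks(ps),
                   tolerance = 1e-9)
    }
  })
  # linearly decaying amplitudes give a negative slope
  dec <- structure(list(times = 0:4, amplitudes = 5 - (0:4)),
                   class = "peak_set")
  expect_true(mean_slope_peaks(dec) < 0)
  dup <- structure(list(times = c(1, 1), amplitudes = c(1, 2)),
                   class = "peak_set")
  expect_error(mean_slope_peaks(dup), "duplicate")
})

test_that("build_feature_matrix has the documented shape and header", {
  gen <- generate_cohort(small_cohort_config(seed = 2, n_subjects = 2))
  cf <- cohort_features(gen$cohort)
  ft <- cf$features
  # 2 subjects x 2 hands x 5 sets x 6 reps
  expect_equal(nrow(ft), 2 * 2 * 5 * 6)
  expect_equal(ncol(ft), 6 + 99)
  expect_true(all(ft$label %in% c("fatigue", "non_fatigue")))
  expect_equal(names(ft)[1:6],
               c("subject_id", "hand", "set_index", "rep_index",
                 "effective_rpe", "label"))
  expect_equal(names(ft)[7:17],
               paste0("ax_", c("min", "max", "mean", "median", "sd",
                               "variance", "kurtosis", "rms", "skewness",
                               "iop", "msp")))
  # variance = sd^2 and min <= median <= max on every row/channel
  for (ch in c("ax", "gx", "yaw")) {
    expect_equal(ft[[paste0(ch, "_variance")]],
                 ft[[paste0(ch, "_sd")]]^2, tolerance = 1e-9)
    expect_true(all(ft[[paste0(ch, "_min")]] <=
                      ft[[paste0(ch, "_median")]] + 1e-12))
    expect_true(all(ft[[paste0(ch, "_median")]] <=
                      ft[[paste0(ch, "_max")]] + 1e-12))
  }
})

test_that("build_feature_matrix on an empty cohort returns the header", {
  ft <- build_feature_matrix(list())
  expect_equal(nrow(ft), 0)
  expect_equal(ncol(ft), 105)
})
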