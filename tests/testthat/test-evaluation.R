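test_that("confusion counts the four cells per the fatigue convention", {
  cc <- confusion(c("fatigue", "fatigue", "non_fatigue", "non_fatigue"),
                  c("fatigue", "non_fatigue", "fatigue", "non_fatigue"))
  expect_equal(c(cc$tp, cc$fn, cc$fp, cc$tn), c(1, 1, 1, 1))
  all_right <- confusion(rep("fatigue", 3), rep("fatigue", 3))
  expect_equal(c(all_right$fp, all_right$fn), c(0, 0))
  # swapping truth and prediction swaps fp and fn
  y1 <- rep(c("fatigue", "non_fatigue"), c(7, 13))
  y2 <- sample(y1)
  a <- confusion(y1, y2)
  b <- confusion(y2, y1)
  expect_equal(a$fp, b$fn)
  expect_equal(a$fn, b$fp)
  expect_error(confusion("fatigue", character(0)), "equal")
})

test_that("metrics implement the printed formulas with 0-denominator
          conventions", {
  m <- metrics(structure(list(tp = 3, fp = 1, fn = 1, tn = 5),
                         class = "confusion_counts"))
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$f1, 0.75)
  degenerate <- metrics(structure(list(tp = 0, fp = 0, fn = 2, tn = 8),
                                  class = "confusion_counts"))
  expect_equal(degenerate$precision, 0)
  expect_equal(degenerate$f1, 0)
})

test_that("metrics agree with a brute-force counting oracle", {
  withr::with_seed(55, {
    for (i in 1:1000) {
      n <- sample(2:60, 1)
      y <- sample(c("fatigue", "non_fatigue"), n, replace = TRUE)
      p <- sample(c("fatigue", "non_fatigue"), n, replace = TRUE)
      m <- metrics(confusion(y, p))
      # oracle: direct counting loops
      tp <- fp <- fn <- tn <- 0
      for (j in seq_len(n)) {
        if (y[j] == "fatigue" && p[j] == "fatigue") tp <- tp + 1
        if (y[j] != "fatigue" && p[j] == "fatigue") fp <- fp + 1
        if (y[j] == "fatigue" && p[j] != "fatigue") fn <- fn + 1
        if (y[j] != "fatigue" && p[j] != "fatigue") tn <- tn + 1
      }
      expect_equal(m$accuracy, (tp + tn) / n)
      expect_equal(m$precision, if (tp + fp > 0) tp / (tp + fp) else 0)
      expect_equal(m$recall, if (tp + fn > 0) tp / (tp + fn) else 0)
    }
  })
})

test_that("accuracy_gain_ratio divides delta by repetitions", {
  expect_equal(round(accuracy_gain_ratio(5.44, 15), 2), 0.36)
  expect_equal(accuracy_gain_ratio(25.96, 8), 3.245)
  expect_equal(accuracy_gain_ratio(0, 7), 0)
  expect_error(accuracy_gain_ratio(1, 0), ">= 1")
})

test_that("comparison_table reproduces pairwise deltas and antisymmetry", {
  acc <- c(cross = 60.08, personalized = 76.08, specific = 88.75)
  d <- comparison_table(acc)
  expect_equal(d["personalized", "cross"], 16.00)
  expect_equal(d["specific", "cross"], 28.67)
  expect_equal(d["specific", "personalized"], 12.67)
  expect_equal(d, -t(d))
  expect_equal(diag(d), c(cross = 0, personalized = 0, specific = 0))
  same <- comparison_table(c(a = 50, b = 50))
  expect_true(all(same == 0))
  expect_error(comparison_table(acc, test_ids = list(1:3, 1:3, 1:4)),
               "different test sets")
})

small_eval_world <- function(seed = 2, n_subjects = 5L) {
  gen <- generate_cohort(small_cohort_config(seed = seed,
                                             n_subjects = n_subjects))
  cohort_features(gen$cohort)
}

test_that("loocv holds each subject out exactly once", {
  cf <- small_eval_world()
  cfg <- model_config("decision_tree", n_rounds = 3, seed = 1)
  res <- loocv(cf$features, cf$traits, similarity_params(0.4, 0.6, 5), cfg)
  ids <- sort(unique(cf$features$subject_id))
  expect_equal(sort(res$folds$subject_id), ids)
  expect_equal(nrow(res$folds), length(ids))
  expect_true(all(res$folds$accuracy >= 0 & res$folds$accuracy <= 1))
  expect_true(res$aggregate$accuracy[["ci_low"]] <=
                res$aggregate$accuracy[["mean"]])
  # fold results do not depend on subject iteration order
  res2 <- loocv(cf$features, cf$traits, similarity_params(0.4, 0.6, 5),
                cfg, subjects = rev(ids))
  expect_equal(res2$folds, res$folds)
})

test_that("loocv on two subjects yields two folds", {
  cf <- small_eval_world(seed = 6, n_subjects = 2L)
  res <- loocv(cf$features, cf$traits, similarity_params(0.4, 0.6, 5),
               model_config("decision_tree", n_rounds = 2, seed = 1))
  expect_equal(nrow(res$folds), 2)
})

test_that("sweep_gamma anchors deltas at gamma = 0 and is deterministic on
          shared grid points", {
  cf <- small_eval_world(seed = 4)
  cfg <- model_config("decision_tree", n_rounds = 2, seed = 2)
  ids <- sort(unique(cf$features$subject_id))[1:2]
  res <- sweep_gamma(cf$features, cf$traits, grid = c(0, 5, 20),
                     config = cfg, subjects = ids)
  expect_equal(res$table$delta_physical[res$table$gamma == 0], 0)
  expect_equal(res$table$delta_signal[res$table$gamma == 0], 0)
  expect_true(res$optimum_gamma %in% res$table$gamma)
  # denser grid leaves shared points unchanged
  res2 <- sweep_gamma(cf$features, cf$traits, grid = c(0, 2, 5, 20),
                      config = cfg, subjects = ids)
  shared <- res2$table[res2$table$gamma %in% c(0, 5, 20), ]
  expect_equal(shared$accuracy_physical, res$table$accuracy_physical)
  expect_equal(shared$accuracy_signal, res$table$accuracy_signal)
  expect_error(sweep_gamma(cf$features, cf$traits, grid = c(1, 2)),
               "include 0")
  expect_error(sweep_gamma(cf$features, cf$traits, grid = numeric(0)),
               "empty")
})

test_that("sweep_alpha_beta covers the unit simplex and matches endpoints", {
  cf <- small_eval_world(seed = 8)
  cfg <- model_config("decision_tree", n_rounds = 2, seed = 3)
  ids <- sort(unique(cf$features$subject_id))[1:2]
  res <- sweep_alpha_beta(cf$features, cf$traits, step = 0.25, gamma = 5,
                          config = cfg, subjects = ids)
  expect_equal(res$table$alpha, seq(0, 1, 0.25))
  expect_equal(res$table$alpha + res$table$beta, rep(1, 5))
  # endpoint equivalence with explicit single-similarity runs
  phys_only <- loocv(cf$features, cf$traits, similarity_params(1, 0, 5),
                     cfg, subjects = ids)$aggregate$accuracy[["mean"]]
  expect_equal(res$table$accuracy[res$table$alpha == 1], phys_only)
  sig_only <- loocv(cf$features, cf$traits, similarity_params(0, 1, 5),
                    cfg, subjects = ids)$aggregate$accuracy[["mean"]]
  expect_equal(res$table$accuracy[res$table$alpha == 0], sig_only)
  # default step gives 21 points including the (0.4, 0.6) optimum
  expect_equal(length(seq(0, 1, 0.05)), 21)
  expect_true(any(abs(seq(0, 1, 0.05) - 0.4) < 1e-12))
  expect_error(sweep_alpha_beta(cf$features, cf$traits, step = 0.3),
               "divide 1")
  expect_error(sweep_alpha_beta(cf$features, cf$traits, step = 0),
               "> 0")
})

test_that("budget_curve has the Table-5 shape and satisfies the AGR
          identity", {
  cf <- small_eval_world(seed = 9, n_subjects = 4L)
  ids <- sort(unique(cf$features$subject_id))[1:2]
  res <- budget_curve(cf$features, cf$traits,
                      params = similarity_params(0.4, 0.6, 5),
                      config = model_config("decision_tree", n_rounds = 2,
                                            seed = 4),
                      subjects = ids)
  expect_equal(nrow(res), 14) # 7 fractions x 2 families
  expect_setequal(unique(res$family), c("personalized", "subject_specific"))
  first <- res[res$fraction == 0, ]
  expect_true(all(is.na(first$delta_accuracy)))
  expect_true(all(is.na(first$agr)))
  later <- res[res$fraction > 0 & !is.na(res$agr), ]
  expect_equal(later$agr * later$n_reps, later$delta_accuracy,
               tolerance = 1e-9)
  expect_error(budget_curve(cf$features, cf$traits, fractions = c(0, 0.7)),
               "<= 0.6")
  expect_error(budget_curve(cf$features, cf$traits, fractions = c(0.1, 0.2)),
               "start at 0")
})
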