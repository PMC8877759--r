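fake_scores <- function(ids, sims) {
  data.frame(other_subject = ids, sim_total = sims,
             stringsAsFactors = FALSE)
}

test_that("weights_from_similarity allocates mass by sim/n and normalizes", {
  sc <- fake_scores(c("A", "B"), c(0.8, 0.2))
  rows <- c(rep("A", 10), rep("B", 10))
  w <- weights_from_similarity(sc, rows)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(sum(w[rows == "A"]), 0.8)
  expect_equal(sum(w[rows == "B"]), 0.2)
  # equal sims, unequal row counts: same per-subject mass, halved per row
  sc2 <- fake_scores(c("A", "B"), c(0.5, 0.5))
  rows2 <- c(rep("A", 20), rep("B", 10))
  w2 <- weights_from_similarity(sc2, rows2)
  expect_equal(sum(w2[rows2 == "A"]), 0.5)
  expect_equal(unique(round(w2[rows2 == "A"] / w2[rows2 == "B"][1], 9)), 0.5)
  # all sims equal: uniform row weights
  w3 <- weights_from_similarity(fake_scores(c("A", "B"), c(0.3, 0.3)),
                                c(rep("A", 5), rep("B", 5)))
  expect_equal(w3, rep(0.1, 10))
  # all-zero similarities fall back to uniform, with a warning
  expect_warning(
    w4 <- weights_from_similarity(fake_scores(c("A", "B"), c(0, 0)),
                                  c("A", "B")),
    "uniform")
  expect_equal(w4, c(0.5, 0.5))
  expect_error(weights_from_similarity(sc, c("A", "Z")), "Z")
})

test_that("select_validation_split reserves the top-ranked subject", {
  sc <- fake_scores(c("A", "B", "C"), c(0.9, 0.5, 0.1))
  sp <- select_validation_split(sc)
  expect_equal(sp$validation_subject, "A")
  expect_setequal(sp$train_subjects, c("B", "C"))
  # tie at the top: lexicographically smaller id
  tie <- fake_scores(c("D", "B", "C"), c(0.7, 0.7, 0.1))
  expect_equal(select_validation_split(tie)$validation_subject, "B")
  two <- fake_scores(c("A", "B"), c(0.2, 0.8))
  expect_length(select_validation_split(two)$train_subjects, 1)
  expect_error(select_validation_split(fake_scores("A", 1)), ">= 2")
})

test_that("budget_to_repetitions reproduces the seven-run schedule", {
  fr <- seq(0, 0.6, by = 0.1)
  expect_equal(budget_to_repetitions(fr, 75), c(0, 8, 15, 23, 30, 38, 45))
  expect_equal(budget_to_repetitions(0.2, 75), 15)
  expect_equal(budget_to_repetitions(0, 75), 0)
  expect_error(budget_to_repetitions(0.7, 75), "\\[0, 0.6\\]")
  expect_error(budget_to_repetitions(0.2, 0), "basis")
})

test_that("mix_budget splits rows without leakage and conserves mass", {
  gen <- default_cohort_features(1)
  ft <- gen$features
  test_rows <- ft[ft$subject_id == "S01", ]
  crowd_rows <- ft[ft$subject_id %in% c("S02", "S03"), ]
  cw <- rep(1 / nrow(crowd_rows), nrow(crowd_rows))
  m0 <- mix_budget(crowd_rows, cw, test_rows, 0)
  expect_equal(nrow(m0$train_rows), nrow(crowd_rows))
  expect_equal(nrow(m0$heldout_rows), nrow(test_rows))
  for (fr in c(0.1, 0.2, 0.4, 0.6)) {
    m <- mix_budget(crowd_rows, cw, test_rows, fr)
    nb <- budget_to_repetitions(fr, nrow(test_rows))
    expect_equal(m$n_budget, nb)
    expect_equal(nrow(m$train_rows), nrow(crowd_rows) + nb)
    expect_equal(nrow(m$heldout_rows), nrow(test_rows) - nb)
    expect_equal(sum(m$train_weights), 1, tolerance = 1e-12)
    # budget mass equals its count share
    in_budget <- m$train_rows$subject_id == "S01"
    expect_equal(sum(m$train_weights[in_budget]),
                 nb / (nrow(crowd_rows) + nb), tolerance = 1e-12)
    # leakage guard: no row on both sides
    key <- function(df) paste(df$subject_id, df$hand, df$set_index,
                              df$rep_index)
    expect_length(intersect(key(m$train_rows), key(m$heldout_rows)), 0)
  }
  # one hand = 75 repetitions, the Table-5 basis: 20% -> 15 reps
  left <- test_rows[test_rows$hand == "left", ]
  expect_equal(mix_budget(crowd_rows, cw, left, 0.2)$n_budget, 15)
})

sep_data <- function(n = 120, seed = 4) {
  withr::with_seed(seed, {
    y <- rep(c("fatigue", "non_fatigue"), each = n / 2)
    x <- matrix(rnorm(n * 5), n, 5)
    x[, 1] <- x[, 1] + ifelse(y == "fatigue", 4, -4)
    colnames(x) <- paste0("f", 1:5)
    list(x = x, y = y)
  })
}

test_that("boosting reaches training accuracy 1 on separable data", {
  d <- sep_data()
  for (learner in c("decision_tree", "neural_net")) {
    m <- train_boosted(d$x, d$y,
                       config = model_config(learner, n_rounds = 3,
                                             ann_epochs = 60, seed = 1))
    expect_equal(predict(m, d$x), d$y)
  }
})

test_that("one uniform round of the DT variant equals a single weighted tree", {
  d <- sep_data(seed = 9)
  cfg <- model_config("decision_tree", n_rounds = 1, seed = 5)
  m <- train_boosted(d$x, d$y, config = cfg)
  tree <- curlfatigue:::fit_weighted_tree(
    d$x, as.integer(d$y == "fatigue"), rep(1 / nrow(d$x), nrow(d$x)),
    max_depth = cfg$tree_max_depth)
  lone <- ifelse(curlfatigue:::predict_tree(tree, d$x) == 1L,
                 "fatigue", "non_fatigue")
  expect_identical(predict(m, d$x), lone)
})

test_that("training is bit-deterministic given the seed", {
  gen <- default_cohort_features(1)
  rows <- gen$features[gen$features$subject_id %in%
                         c("S02", "S03", "S04"), ]
  x <- curlfatigue:::feature_cols(rows)
  for (learner in c("decision_tree", "neural_net")) {
    cfg <- model_config(learner, n_rounds = 2, ann_epochs = 30,
                        ann_hidden_units = 4, seed = 11)
    m1 <- train_boosted(x, rows$label, config = cfg)
    m2 <- train_boosted(x, rows$label, config = cfg)
    expect_identical(predict(m1, x), predict(m2, x))
  }
})

test_that("single-class training sets are rejected by name", {
  d <- sep_data()
  keep <- d$y == "fatigue"
  expect_error(train_boosted(d$x[keep, ], d$y[keep]), "non_fatigue")
  expect_error(train_boosted(d$x[!keep, ], d$y[!keep]), "'fatigue'")
})

test_that("uniform-weight personalized training equals cross-subject
          training (alpha = beta = 0 semantics)", {
  gen <- default_cohort_features(1)
  rows <- gen$features[gen$features$subject_id %in%
                         c("S02", "S03", "S04", "S05"), ]
  test_rows <- gen$features[gen$features$subject_id == "S01", ]
  xtest <- curlfatigue:::feature_cols(test_rows)
  for (learner in c("decision_tree", "neural_net")) {
    cfg <- model_config(learner, n_rounds = 2, ann_epochs = 30,
                        ann_hidden_units = 4, seed = 3)
    w <- rep(1 / nrow(rows), nrow(rows))
    mp <- train_personalized(rows, w, config = cfg)
    mc <- train_cross_subject(rows, config = cfg)
    expect_identical(predict(mp, xtest), predict(mc, xtest))
  }
})

test_that("boosting keeps a normalized distribution every round", {
  # re-run the update manually against the model's stored vote weights
  d <- sep_data(n = 80, seed = 12)
  noisy_y <- d$y
  withr::with_seed(2, {
    flip <- sample(length(noisy_y), 12)
    noisy_y[flip] <- ifelse(noisy_y[flip] == "fatigue", "non_fatigue",
                            "fatigue")
  })
  cfg <- model_config("decision_tree", n_rounds = 8, seed = 7)
  m <- train_boosted(d$x, noisy_y, config = cfg)
  y01 <- as.integer(noisy_y == "fatigue")
  w <- rep(1 / nrow(d$x), nrow(d$x))
  for (k in seq_along(m$learners)) {
    expect_equal(sum(w), 1, tolerance = 1e-9)
    pred <- curlfatigue:::predict_tree(m$learners[[k]], d$x)
    err <- sum(w[pred != y01])
    if (err > 1e-10 && err < 0.5 && k < length(m$learners)) {
      w <- w * exp(m$alphas[k] * (pred != y01))
      w <- w / sum(w)
    }
  }
})

test_that("train_subject_specific honors the fraction boundary", {
  gen <- default_cohort_features(1)
  test_rows <- gen$features[gen$features$subject_id == "S01", ]
  cfg <- model_config("decision_tree", n_rounds = 2, seed = 1)
  m <- train_subject_specific(test_rows, 1, cfg)
  expect_s3_class(m, "boosted_fatigue_model")
  expect_error(train_subject_specific(test_rows, 0, cfg), "no training rows")
})
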