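# Metrics and the three experiment drivers: LOOCV comparison, gamma and
# alpha/beta sweeps, and test-subject data-budget curves.

#' Confusion counts for fatigue detection
#'
#' `fatigue` is the positive class: `tp` = true fatigue, `fp` = false
#' fatigue, `fn` = false non-fatigue, `tn` = true non-fatigue.
#'
#' @param y_true,y_pred Label vectors (`"fatigue"` / `"non_fatigue"`),
#'   equal lengths >= 1.
#' @return Object of class `confusion_counts`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || !length(y_true)) {
    stop("confusion(): label vectors must be equal non-zero length",
         call. = FALSE)
  }
  tpos <- y_true == "fatigue"
  ppos <- y_pred == "fatigue"
  structure(list(tp = sum(tpos & ppos), fp = sum(!tpos & ppos),
                 fn = sum(tpos & !ppos), tn = sum(!tpos & !ppos)),
            class = "confusion_counts")
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' Precision, recall and F1 are defined as 0 when their denominator is 0.
#'
#' @param cc A `confusion_counts`.
#' @return List with `accuracy`, `precision`, `recall`, `f1` (fractions in
#'   `[0, 1]`).
#' @export
metrics <- function(cc) {
  total <- cc$tp + cc$fp + cc$fn + cc$tn
  if (total < 1L) stop("metrics(): empty confusion counts", call. = FALSE)
  prec <- if (cc$tp + cc$fp > 0) cc$tp / (cc$tp + cc$fp) else 0
  rec <- if (cc$tp + cc$fn > 0) cc$tp / (cc$tp + cc$fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(accuracy = (cc$tp + cc$tn) / total, precision = prec, recall = rec,
       f1 = f1)
}

#' Accuracy gain ratio (AGR)
#'
#' Accuracy gained per test-subject repetition added to training:
#' `delta_accuracy / n_reps`.
#'
#' @param delta_accuracy Accuracy change in percentage points.
#' @param n_reps Number of test-subject repetitions consumed (>= 1).
#' @return AGR in percentage points per repetition.
#' @export
accuracy_gain_ratio <- function(delta_accuracy, n_reps) {
  if (any(n_reps < 1)) {
    stop("accuracy_gain_ratio(): n_reps must be >= 1", call. = FALSE)
  }
  delta_accuracy / n_reps
}

# ---- shared fold machinery --------------------------------------------

# Crowd description for rank_crowd(): traits plus each subject's
# similarity-sample feature block (earliest set, reference channel).
crowd_blocks <- function(features, traits, ids, channel = "gx") {
  out <- lapply(ids, function(id) {
    list(traits = traits[[id]],
         features = signal_feature_block(features, id, channel = channel))
  })
  stats::setNames(out, ids)
}

# One leave-one-subject-out fold of the (possibly personalized) pipeline.
# With alpha = beta = 0 all similarities are zero, ranking ties resolve
# lexicographically and the weights fall back to uniform -- the standard
# cross-subject pipeline.
run_fold <- function(features, traits, test_id, params, config,
                     sim_channel = "gx", normalize_signal = TRUE) {
  ids <- sort(unique(features$subject_id))
  crowd_ids <- setdiff(ids, test_id)
  crowd <- crowd_blocks(features, traits, crowd_ids, channel = sim_channel)
  test_block <- signal_feature_block(features, test_id,
                                     channel = sim_channel)
  scores <- rank_crowd(traits[[test_id]], test_block, crowd,
                       params = params, test_id = test_id,
                       normalize_signal = normalize_signal)
  # a singleton crowd cannot spare a validation subject; train on it all
  split <- if (nrow(scores) >= 2L) select_validation_split(scores) else
    list(validation_subject = NA_character_,
         train_subjects = scores$other_subject)
  train_rows <- features[features$subject_id %in% split$train_subjects, ]
  w <- weights_from_similarity(
    scores[scores$other_subject %in% split$train_subjects, ],
    train_rows$subject_id,
    quiet = params$alpha == 0 && params$beta == 0)
  model <- train_personalized(train_rows, w, config = config)
  test_rows <- features[features$subject_id == test_id, ]
  pred <- predict(model, feature_cols(test_rows))
  list(test_id = test_id, scores = scores,
       validation_subject = split$validation_subject,
       y_true = test_rows$label, y_pred = pred,
       metrics = metrics(confusion(test_rows$label, pred)))
}

aggregate_ci <- function(vals) {
  n <- length(vals)
  m <- mean(vals)
  half <- if (n > 1) 1.96 * stats::sd(vals) / sqrt(n) else NA_real_
  c(mean = m, ci_low = m - half, ci_high = m + half)
}

#' Leave-one-subject-out cross-validation
#'
#' Each subject is held out once; the remaining subjects form the crowd
#' (top-similarity subject reserved for validation, rest training). Folds
#' are seeded deterministically from `config$seed` plus the held-out
#' subject's rank in the sorted id list, so results do not depend on
#' iteration order. Folds whose held-out subject carries a single class are
#' skipped with a warning.
#'
#' @param features Feature table from [build_feature_matrix()].
#' @param traits Named list of [physical_traits()], keyed by subject id.
#' @param params A [similarity_params()]; use `alpha = beta = 0` for the
#'   plain cross-subject baseline.
#' @param config A [model_config()].
#' @param subjects Optional subset of subject ids to use as held-out folds
#'   (runtime scaling for sweeps); defaults to every subject.
#' @param sim_channel Channel whose 11 features feed the signal similarity.
#' @param normalize_signal Passed to [rank_crowd()].
#' @return List with `folds` (per-fold data frame), `aggregate` (mean and
#'   95% normal-approximation CI per metric) and `n_skipped`.
#' @export
loocv <- function(features, traits, params = similarity_params(),
                  config = model_config(), subjects = NULL,
                  sim_channel = "gx", normalize_signal = TRUE) {
  ids <- sort(unique(features$subject_id))
  if (length(ids) < 2L) stop("loocv(): need >= 2 subjects", call. = FALSE)
  test_ids <- if (is.null(subjects)) ids else {
    stopifnot(all(subjects %in% ids))
    sort(subjects)
  }
  rows <- list()
  n_skipped <- 0L
  for (id in test_ids) {
    labs <- unique(features$label[features$subject_id == id])
    if (length(labs) < 2L) {
      warning(sprintf("loocv(): skipping single-class fold '%s'", id),
              call. = FALSE)
      n_skipped <- n_skipped + 1L
      next
    }
    fold_cfg <- config
    fold_cfg$seed <- config$seed + match(id, ids)
    fold <- run_fold(features, traits, id, params, fold_cfg,
                     sim_channel = sim_channel,
                     normalize_signal = normalize_signal)
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = id, accuracy = fold$metrics$accuracy,
      precision = fold$metrics$precision, recall = fold$metrics$recall,
      f1 = fold$metrics$f1)
  }
  folds <- do.call(rbind, rows)
  agg <- lapply(c("accuracy", "precision", "recall", "f1"), function(mname) {
    aggregate_ci(folds[[mname]])
  })
  names(agg) <- c("accuracy", "precision", "recall", "f1")
  list(folds = folds, aggregate = agg, n_skipped = n_skipped)
}

#' Sweep the exponential scaling parameter gamma
#'
#' For every grid value, runs the physical-only (`alpha = 1`) and
#' signal-only (`alpha = 0`) personalized pipelines and records the mean
#' LOOCV accuracy. `delta_accuracy` is measured against the accuracy at
#' `gamma = 0` (the grid must contain 0); the reported optimum is the
#' smallest gamma attaining the maximum mean delta across the two variants.
#'
#' @inheritParams loocv
#' @param grid Gamma values to evaluate, containing 0.
#' @return List with `table` (gamma, variant accuracies, deltas,
#'   `delta_mean`) and `optimum_gamma`.
#' @export
sweep_gamma <- function(features, traits, grid = 0:30,
                        config = model_config(), subjects = NULL,
                        sim_channel = "gx", normalize_signal = TRUE) {
  if (!length(grid)) stop("sweep_gamma(): empty grid", call. = FALSE)
  if (!any(grid == 0)) stop("sweep_gamma(): grid must include 0",
                            call. = FALSE)
  grid <- sort(unique(grid))
  acc_phy <- acc_sig <- numeric(length(grid))
  for (i in seq_along(grid)) {
    p_phy <- similarity_params(alpha = 1, beta = 0, gamma = grid[i])
    p_sig <- similarity_params(alpha = 0, beta = 1, gamma = grid[i])
    acc_phy[i] <- loocv(features, traits, p_phy, config,
                        subjects = subjects, sim_channel = sim_channel,
                        normalize_signal = normalize_signal
                        )$aggregate$accuracy[["mean"]]
    acc_sig[i] <- loocv(features, traits, p_sig, config,
                        subjects = subjects, sim_channel = sim_channel,
                        normalize_signal = normalize_signal
                        )$aggregate$accuracy[["mean"]]
  }
  ref_phy <- acc_phy[grid == 0]
  ref_sig <- acc_sig[grid == 0]
  tab <- data.frame(gamma = grid, accuracy_physical = acc_phy,
                    accuracy_signal = acc_sig,
                    delta_physical = acc_phy - ref_phy,
                    delta_signal = acc_sig - ref_sig)
  tab$delta_mean <- (tab$delta_physical + tab$delta_signal) / 2
  best <- min(tab$gamma[tab$delta_mean == max(tab$delta_mean)])
  list(table = tab, optimum_gamma = best)
}

#' Sweep the alpha/beta blend under alpha + beta = 1
#'
#' @inheritParams loocv
#' @param step Grid step; must divide 1 exactly (default 0.05, giving 21
#'   points including the endpoints and (0.4, 0.6)).
#' @param gamma Gamma used at every grid point (default 14).
#' @return List with `table` (alpha, beta, accuracy) and `optimum`
#'   (`alpha`, `beta`; smallest alpha wins ties).
#' @export
sweep_alpha_beta <- function(features, traits, step = 0.05, gamma = 14,
                             config = model_config(), subjects = NULL,
                             sim_channel = "gx", normalize_signal = TRUE) {
  if (step <= 0) stop("sweep_alpha_beta(): step must be > 0", call. = FALSE)
  k <- 1 / step
  if (abs(k - round(k)) > 1e-9) {
    stop("sweep_alpha_beta(): step must divide 1 exactly", call. = FALSE)
  }
  alphas <- seq(0, 1, by = step)
  acc <- numeric(length(alphas))
  for (i in seq_along(alphas)) {
    p <- similarity_params(alpha = alphas[i], beta = 1 - alphas[i],
                           gamma = gamma)
    acc[i] <- loocv(features, traits, p, config, subjects = subjects,
                    sim_channel = sim_channel,
                    normalize_signal = normalize_signal
                    )$aggregate$accuracy[["mean"]]
  }
  tab <- data.frame(alpha = alphas, beta = 1 - alphas, accuracy = acc)
  best_alpha <- min(tab$alpha[tab$accuracy == max(tab$accuracy)])
  list(table = tab,
       optimum = list(alpha = best_alpha, beta = 1 - best_alpha))
}

#' Test-subject data-budget curves
#'
#' Seven runs (fractions 0, 0.1, ..., 0.6 by default): at each fraction the
#' first `round(fraction * n)` chronological test-subject repetitions join
#' the personalized model's training set (and form the subject-specific
#' model's entire training set); both models are evaluated on the remaining
#' held-out repetitions and accuracies are averaged over the evaluated
#' subjects. `delta_accuracy` is run-over-previous-run and
#' `agr = delta_accuracy / n_reps`. The subject-specific model is
#' untrainable at fraction 0 and reports `NA` there.
#'
#' @inheritParams loocv
#' @param fractions Ascending fractions starting at 0, all <= 0.6.
#' @return Data frame with `family`, `fraction`, `n_reps`, `accuracy`,
#'   `delta_accuracy`, `agr` (accuracies in percent).
#' @export
budget_curve <- function(features, traits,
                         fractions = seq(0, 0.6, by = 0.1),
                         params = similarity_params(),
                         config = model_config(), subjects = NULL,
                         sim_channel = "gx", normalize_signal = TRUE) {
  if (any(fractions > 0.6 + 1e-9) || is.unsorted(fractions) ||
      fractions[1] != 0) {
    stop("budget_curve(): fractions must be ascending, start at 0 and stay <= 0.6",
         call. = FALSE)
  }
  ids <- sort(unique(features$subject_id))
  test_ids <- if (is.null(subjects)) ids else sort(subjects)
  acc <- array(NA_real_,
               dim = c(length(test_ids), length(fractions), 2),
               dimnames = list(test_ids, NULL,
                               c("personalized", "subject_specific")))
  nrep_mat <- matrix(0L, length(test_ids), length(fractions))
  for (si in seq_along(test_ids)) {
    id <- test_ids[si]
    crowd_ids <- setdiff(ids, id)
    crowd <- crowd_blocks(features, traits, crowd_ids,
                          channel = sim_channel)
    test_block <- signal_feature_block(features, id, channel = sim_channel)
    scores <- rank_crowd(traits[[id]], test_block, crowd, params = params,
                         test_id = id, normalize_signal = normalize_signal)
    split <- select_validation_split(scores)
    crowd_rows <- features[features$subject_id %in% split$train_subjects, ]
    w <- weights_from_similarity(
      scores[scores$other_subject %in% split$train_subjects, ],
      crowd_rows$subject_id,
      quiet = params$alpha == 0 && params$beta == 0)
    test_rows <- features[features$subject_id == id, ]
    fold_cfg <- config
    fold_cfg$seed <- config$seed + match(id, ids)
    for (fi in seq_along(fractions)) {
      mix <- mix_budget(crowd_rows, w, test_rows, fractions[fi])
      nrep_mat[si, fi] <- mix$n_budget
      if (!nrow(mix$heldout_rows)) next
      pers <- train_personalized(mix$train_rows, mix$train_weights,
                                 config = fold_cfg)
      pred_p <- predict(pers, feature_cols(mix$heldout_rows))
      acc[si, fi, "personalized"] <-
        metrics(confusion(mix$heldout_rows$label, pred_p))$accuracy
      if (mix$n_budget > 0L &&
          length(unique(test_rows$label[seq_len(mix$n_budget)])) == 2L) {
        spec <- train_subject_specific(test_rows, fractions[fi],
                                       config = fold_cfg)
        pred_s <- predict(spec, feature_cols(mix$heldout_rows))
        acc[si, fi, "subject_specific"] <-
          metrics(confusion(mix$heldout_rows$label, pred_s))$accuracy
      }
    }
  }
  out <- list()
  for (family in c("subject_specific", "personalized")) {
    a <- 100 * colMeans(acc[, , family, drop = FALSE], na.rm = TRUE)
    a[is.nan(a)] <- NA_real_
    n_reps <- as.integer(round(colMeans(nrep_mat)))
    delta <- c(NA_real_, diff(a))
    agr <- ifelse(n_reps > 0 & !is.na(delta), delta / n_reps, NA_real_)
    out[[family]] <- data.frame(
      family = family, fraction = fractions, n_reps = n_reps,
      accuracy = as.numeric(a), delta_accuracy = delta, agr = agr)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pairwise accuracy deltas between model families
#'
#' @param accuracies Named numeric vector of accuracies (percent), e.g.
#'   cross-subject / personalized / subject-specific.
#' @param test_ids Optional list of held-out row-id vectors, one per model;
#'   if given, all must be identical (same evaluation rows).
#' @return Square matrix `D` with `D[i, j] = accuracies[i] - accuracies[j]`.
#' @export
comparison_table <- function(accuracies, test_ids = NULL) {
  if (!is.null(test_ids)) {
    ref <- test_ids[[1]]
    same <- vapply(test_ids, function(v) identical(v, ref), TRUE)
    if (!all(same)) {
      stop("comparison_table(): models evaluated on different test sets",
           call. = FALSE)
    }
  }
  d <- outer(accuracies, accuracies, "-")
  dimnames(d) <- list(names(accuracies), names(accuracies))
  d
}
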