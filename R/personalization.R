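# From similarity scores to a weighted training set and trained models.

feature_cols <- function(df) as.matrix(df[, feature_colnames()])

#' Per-row training weights from similarity scores
#'
#' Each crowd subject's rows share one weight proportional to
#' `sim_total / n_rows`, so a subject's total mass is proportional to its
#' similarity regardless of how many repetitions it contributed. Weights
#' are normalized to sum to 1. If every similarity is zero (the
#' cross-subject `alpha = beta = 0` mode) the fallback is uniform weights.
#'
#' @param scores Data frame from [rank_crowd()] (needs `other_subject`,
#'   `sim_total`).
#' @param row_subject_ids Character vector: the subject id of every training
#'   row, each id present in `scores`.
#' @param quiet Suppress the all-zero-fallback warning.
#' @return Numeric weights, one per row, summing to 1.
#' @export
weights_from_similarity <- function(scores, row_subject_ids, quiet = FALSE) {
  counts <- table(row_subject_ids)
  miss <- setdiff(names(counts), scores$other_subject)
  if (length(miss)) {
    stop(sprintf("weights_from_similarity(): no score for subject(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  sims <- stats::setNames(scores$sim_total, scores$other_subject)
  if (all(sims[names(counts)] == 0)) {
    if (!quiet) {
      warning("weights_from_similarity(): all similarities zero; falling back to uniform weights",
              call. = FALSE)
    }
    w <- rep(1, length(row_subject_ids))
    return(w / sum(w))
  }
  per_row <- sims[row_subject_ids] / as.numeric(counts[row_subject_ids])
  per_row <- as.numeric(per_row)
  per_row / sum(per_row)
}

#' Split the crowd into training and validation subjects
#'
#' The single top-ranked (most similar) crowd subject is reserved for
#' validation/tuning; everyone else trains. Ties at the top break
#' lexicographically by id.
#'
#' @param scores Data frame from [rank_crowd()].
#' @return List with `validation_subject` (one id) and `train_subjects`.
#' @export
select_validation_split <- function(scores) {
  if (nrow(scores) < 2L) {
    stop("select_validation_split(): need >= 2 crowd subjects",
         call. = FALSE)
  }
  top <- max(scores$sim_total)
  cand <- sort(scores$other_subject[scores$sim_total == top])
  val <- cand[1]
  list(validation_subject = val,
       train_subjects = setdiff(scores$other_subject, val))
}

#' Test-subject data budget in repetitions
#'
#' `round-half-up(fraction * basis)`: at the default basis of 75
#' repetitions per hand the seven budget runs 0%..60% give
#' 0, 8, 15, 23, 30, 38, 45 repetitions.
#'
#' @param fraction Budget fraction in `[0, 0.6]`.
#' @param basis Repetition count the fraction applies to (default 75).
#' @return Integer repetition count.
#' @export
budget_to_repetitions <- function(fraction, basis = 75L) {
  if (any(fraction < 0) || any(fraction > 0.6 + 1e-9)) {
    stop("budget_to_repetitions(): fraction must lie in [0, 0.6]",
         call. = FALSE)
  }
  if (basis <= 0) stop("budget_to_repetitions(): basis must be > 0",
                       call. = FALSE)
  as.integer(floor(fraction * basis + 0.5))
}

#' Blend crowd rows with a test-subject data budget
#'
#' The first `budget_to_repetitions(fraction, nrow(test_rows))` test-subject
#' rows (chronological) join the training set; the rest are held out for
#' evaluation. Budget rows enter with uniform per-row weight whose total
#' mass equals their count's share of the combined training set; the crowd
#' weights are rescaled to the complementary mass. No row ever appears on
#' both sides.
#'
#' @param crowd_rows Feature-table rows from the crowd.
#' @param crowd_weights Per-row weights for `crowd_rows` (sum 1).
#' @param test_rows The test subject's feature-table rows, chronological.
#' @param fraction Budget fraction in `[0, 0.6]`.
#' @return List with `train_rows`, `train_weights` (sum 1), `heldout_rows`
#'   and `n_budget`.
#' @export
mix_budget <- function(crowd_rows, crowd_weights, test_rows, fraction) {
  stopifnot(nrow(crowd_rows) == length(crowd_weights))
  n_test <- nrow(test_rows)
  n_budget <- budget_to_repetitions(fraction, n_test)
  if (n_budget > n_test) {
    stop("mix_budget(): budget exceeds available test-subject rows",
         call. = FALSE)
  }
  n_crowd <- nrow(crowd_rows)
  if (n_budget == 0L) {
    return(list(train_rows = crowd_rows,
                train_weights = crowd_weights / sum(crowd_weights),
                heldout_rows = test_rows, n_budget = 0L))
  }
  total <- n_crowd + n_budget
  budget_rows <- test_rows[seq_len(n_budget), , drop = FALSE]
  w <- c(crowd_weights / sum(crowd_weights) * (n_crowd / total),
         rep(1 / total, n_budget))
  list(train_rows = rbind(crowd_rows, budget_rows),
       train_weights = w / sum(w),
       heldout_rows = test_rows[-seq_len(n_budget), , drop = FALSE],
       n_budget = n_budget)
}

#' Train the personalized (similarity-weighted) classifier
#'
#' @param train_rows Feature-table rows.
#' @param train_weights Initial sample weights (sum 1).
#' @param config A [model_config()].
#' @return A `boosted_fatigue_model`.
#' @export
train_personalized <- function(train_rows, train_weights,
                               config = model_config()) {
  train_boosted(feature_cols(train_rows), train_rows$label,
                weights = train_weights, config = config)
}

#' Train a plain cross-subject classifier (uniform weights)
#'
#' @inheritParams train_personalized
#' @export
train_cross_subject <- function(train_rows, config = model_config()) {
  train_boosted(feature_cols(train_rows), train_rows$label,
                weights = NULL, config = config)
}

#' Train a subject-specific classifier on the test subject's own rows
#'
#' @param test_rows The test subject's feature-table rows, chronological.
#' @param fraction Fraction of rows (from the start) to train on; 1.0 uses
#'   all supplied rows.
#' @param config A [model_config()].
#' @return A `boosted_fatigue_model`.
#' @export
train_subject_specific <- function(test_rows, fraction = 1,
                                   config = model_config()) {
  n <- if (fraction >= 1) nrow(test_rows) else
    budget_to_repetitions(fraction, nrow(test_rows))
  if (n < 1L) {
    stop("train_subject_specific(): no training rows at this fraction",
         call. = FALSE)
  }
  rows <- test_rows[seq_len(n), , drop = FALSE]
  train_boosted(feature_cols(rows), rows$label, weights = NULL,
                config = config)
}
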