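# Discrete two-class AdaBoost initialized from (possibly non-uniform)
# sample weights. Trees consume the boosting distribution natively; the
# neural net cannot, so it is fit on a weighted resample each round.

LABEL_LEVELS <- c("fatigue", "non_fatigue")

#' Classifier configuration
#'
#' @param base_learner `"decision_tree"` or `"neural_net"`.
#' @param n_rounds Boosting rounds; defaults to 50 for trees and 10 for the
#'   neural net.
#' @param learning_rate Shrinkage applied to the per-round vote weights.
#' @param tree_max_depth Maximum tree depth (default 3).
#' @param ann_hidden_units Hidden-layer width (default 16).
#' @param ann_epochs Backprop epochs per round (default 200).
#' @param seed RNG seed; training is bit-deterministic given the seed.
#' @return Object of class `model_config`.
#' @export
model_config <- function(base_learner = c("decision_tree", "neural_net"),
                         n_rounds = NULL, learning_rate = 1,
                         tree_max_depth = 3L, ann_hidden_units = 16L,
                         ann_epochs = 200L, seed = 1L) {
  base_learner <- match.arg(base_learner)
  if (is.null(n_rounds)) {
    n_rounds <- if (base_learner == "decision_tree") 50L else 10L
  }
  if (n_rounds < 1L) stop("model_config(): n_rounds must be >= 1",
                          call. = FALSE)
  structure(list(base_learner = base_learner, n_rounds = as.integer(n_rounds),
                 learning_rate = learning_rate,
                 tree_max_depth = as.integer(tree_max_depth),
                 ann_hidden_units = as.integer(ann_hidden_units),
                 ann_epochs = as.integer(ann_epochs),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Train a boosted fatigue classifier
#'
#' Discrete AdaBoost whose round-1 distribution is `weights` (not uniform):
#' this is where the similarity weighting enters the learner. Per-round
#' updates follow the standard exponential reweighting; rounds performing
#' at or below chance terminate the loop.
#'
#' @param x Numeric feature matrix (rows = repetitions).
#' @param y Labels, values `"fatigue"` / `"non_fatigue"`, both classes
#'   present.
#' @param weights Initial sample weights (>= 0, not all zero); uniform when
#'   `NULL`. Normalized internally to sum to 1.
#' @param config A [model_config()].
#' @return Object of class `boosted_fatigue_model` with a
#'   [predict.boosted_fatigue_model()] method.
#' @export
train_boosted <- function(x, y, weights = NULL, config = model_config()) {
  x <- as.matrix(x)
  y <- as.character(y)
  n <- nrow(x)
  if (length(y) != n) stop("train_boosted(): x/y length mismatch",
                           call. = FALSE)
  for (lev in LABEL_LEVELS) {
    if (!any(y == lev)) {
      stop(sprintf("train_boosted(): training set lacks class '%s'", lev),
           call. = FALSE)
    }
  }
  y01 <- as.integer(y == "fatigue")
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0) || sum(weights) <= 0) {
    stop("train_boosted(): weights must be >= 0 with positive sum",
         call. = FALSE)
  }
  w <- weights / sum(weights)
  eps <- 1e-10
  learners <- list()
  alphas <- numeric(0)
  with_seed(config$seed, {
    for (m in seq_len(config$n_rounds)) {
      if (config$base_learner == "decision_tree") {
        fit <- fit_weighted_tree(x, y01, w,
                                 max_depth = config$tree_max_depth)
        pred <- predict_tree(fit, x)
      } else {
        idx <- sample.int(n, n, replace = TRUE, prob = w)
        fit <- fit_mlp(x[idx, , drop = FALSE], y01[idx],
                       hidden = config$ann_hidden_units,
                       epochs = config$ann_epochs)
        pred <- predict_mlp(fit, x)
      }
      err <- sum(w[pred != y01])
      if (err >= 0.5) {
        if (!length(learners)) {          # keep something rather than nothing
          learners[[1L]] <- fit
          alphas <- eps
        }
        break
      }
      alpha <- config$learning_rate * log((1 - max(err, eps)) / max(err, eps))
      learners[[length(learners) + 1L]] <- fit
      alphas <- c(alphas, alpha)
      if (err <= eps) break
      w <- w * exp(alpha * (pred != y01))
      w <- w / sum(w)
    }
  })
  structure(list(learners = learners, alphas = alphas, config = config,
                 n_features = ncol(x), feature_names = colnames(x)),
            class = "boosted_fatigue_model")
}

#' Predict fatigue labels
#'
#' @param object A `boosted_fatigue_model`.
#' @param newdata Feature matrix with the training columns.
#' @param ... Unused.
#' @return Character vector of `"fatigue"` / `"non_fatigue"`.
#' @export
predict.boosted_fatigue_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (!is.null(object$feature_names) && !is.null(colnames(x))) {
    x <- x[, object$feature_names, drop = FALSE]
  }
  score <- numeric(nrow(x))
  for (m in seq_along(object$learners)) {
    fit <- object$learners[[m]]
    pred <- if (inherits(fit, "cf_tree")) predict_tree(fit, x) else
      predict_mlp(fit, x)
    score <- score + object$alphas[m] * (2 * pred - 1)
  }
  ifelse(score > 0, "fatigue", "non_fatigue")
}
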