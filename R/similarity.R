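# Physical / signal / total similarity between a test subject and a crowd.
#
# Distances are Manhattan; similarity is exp(-gamma * d) (the universal law
# of generalization); total similarity is the convex blend
# alpha * sim_phy + beta * sim_sig with alpha + beta = 1.

#' Similarity parameters
#'
#' `alpha + beta = 1` is enforced at construction. The special pair
#' `alpha = beta = 0` is also accepted: it switches similarity off entirely
#' and mimics a standard (unweighted) cross-subject pipeline.
#'
#' @param alpha Weight of the physical similarity, in `[0, 1]`
#'   (default 0.4, the selected optimum).
#' @param beta Weight of the signal similarity, in `[0, 1]` (default 0.6).
#' @param gamma Exponential scaling parameter, >= 0 (default 14, the value
#'   at which the sweep peaks).
#' @return Object of class `similarity_params`.
#' @export
similarity_params <- function(alpha = 0.4, beta = 0.6, gamma = 14) {
  if (alpha < 0 || alpha > 1 || beta < 0 || beta > 1) {
    stop("similarity_params(): alpha and beta must lie in [0, 1]",
         call. = FALSE)
  }
  s <- alpha + beta
  if (!(abs(s - 1) < 1e-9 || s == 0)) {
    stop("similarity_params(): alpha + beta must equal 1 (or both be 0 for the cross-subject mode)",
         call. = FALSE)
  }
  if (gamma < 0) {
    stop("similarity_params(): gamma must be >= 0", call. = FALSE)
  }
  structure(list(alpha = alpha, beta = beta, gamma = gamma),
            class = "similarity_params")
}

#' Fit min-max normalization statistics on training data
#'
#' @param x Numeric matrix or data frame of training rows (>= 1 row).
#' @return Object of class `minmax_stats` with per-column `min` and `max`.
#' @export
fit_minmax <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 1L) stop("fit_minmax(): empty training set", call. = FALSE)
  structure(list(min = apply(x, 2, min), max = apply(x, 2, max)),
            class = "minmax_stats")
}

#' Apply a fitted min-max transform
#'
#' Maps training-range values into `[0, 1]`; out-of-range query values are
#' clipped. Constant training dimensions map to 0.
#'
#' @param x Matrix/data frame (or vector) to transform.
#' @param stats A `minmax_stats` from [fit_minmax()].
#' @return Matrix of the same shape with entries in `[0, 1]`.
#' @export
apply_minmax <- function(x, stats) {
  one_row <- is.null(dim(x))
  x <- if (one_row) matrix(x, nrow = 1) else as.matrix(x)
  rng <- stats$max - stats$min
  out <- sweep(x, 2, stats$min, "-")
  pos <- rng > 0
  out[, pos] <- sweep(out[, pos, drop = FALSE], 2, rng[pos], "/")
  out[, !pos] <- 0
  out <- pmin(pmax(out, 0), 1)
  if (one_row) out[1, ] else out
}

#' Manhattan distance between two normalized physical-trait vectors
#'
#' @param vq,vp Length-4 vectors (age, height, weight, BMI), entries in
#'   `[0, 1]`.
#' @return Non-negative scalar distance.
#' @export
physical_distance <- function(vq, vp) {
  if (length(vq) != 4L || length(vp) != 4L) {
    stop("physical_distance(): trait vectors must have length 4",
         call. = FALSE)
  }
  sum(abs(vq - vp))
}

#' Manhattan distance between two subjects' repetition feature blocks
#'
#' Sums `|fq[l, k] - fp[l, k]|` over the eleven features k and the
#' repetitions l, pairing repetitions chronologically and truncating to the
#' shorter block (L = min of the two repetition counts).
#'
#' @param fq,fp Matrices with 11 feature columns, one row per repetition
#'   (>= 1 row each).
#' @return Non-negative scalar distance.
#' @export
signal_distance <- function(fq, fp) {
  fq <- as.matrix(fq)
  fp <- as.matrix(fp)
  if (nrow(fq) < 1L || nrow(fp) < 1L) {
    stop("signal_distance(): each subject needs >= 1 repetition",
         call. = FALSE)
  }
  if (ncol(fq) != ncol(fp)) {
    stop("signal_distance(): feature dimensions differ", call. = FALSE)
  }
  L <- min(nrow(fq), nrow(fp))
  sum(abs(fq[seq_len(L), , drop = FALSE] - fp[seq_len(L), , drop = FALSE]))
}

#' Exponential similarity from a distance
#'
#' `sim = exp(-gamma * d)`, in `(0, 1]`. At `gamma = 0` (or `d = 0`) the
#' similarity is 1.
#'
#' @param d Distance, >= 0.
#' @param gamma Scaling parameter, >= 0.
#' @return Similarity in `(0, 1]`. Vectorised over `d`.
#' @export
similarity_from_distance <- function(d, gamma) {
  if (any(d < 0) || gamma < 0) {
    stop("similarity_from_distance(): d and gamma must be >= 0",
         call. = FALSE)
  }
  exp(-gamma * d)
}

#' Total similarity blend
#'
#' @param sim_phy,sim_sig Similarities in `[0, 1]`.
#' @param params A [similarity_params()].
#' @return `alpha * sim_phy + beta * sim_sig`.
#' @export
total_similarity <- function(sim_phy, sim_sig, params = similarity_params()) {
  stopifnot(inherits(params, "similarity_params"))
  params$alpha * sim_phy + params$beta * sim_sig
}

# Extract a subject's similarity-sample feature block: the eleven features
# of `channel` over the repetitions of the subject's earliest recorded set
# (one set ~ 20% of the subject's data), in chronological order.
signal_feature_block <- function(feature_table, subject_id,
                                 channel = "gx", hand = NULL) {
  rows <- feature_table[feature_table$subject_id == subject_id, ]
  if (!is.null(hand)) rows <- rows[rows$hand == hand, ]
  if (!nrow(rows)) {
    stop(sprintf("signal_feature_block(): no rows for subject '%s'",
                 subject_id), call. = FALSE)
  }
  first_hand <- sort(unique(rows$hand))[1]
  rows <- rows[rows$hand == first_hand, ]
  first_set <- min(rows$set_index)
  rows <- rows[rows$set_index == first_set, ]
  rows <- rows[order(rows$rep_index), ]
  as.matrix(rows[, paste(channel, FEATURE_NAMES, sep = "_")])
}

#' Rank a crowd by total similarity to a test subject
#'
#' Normalization (min-max) is fitted on the crowd only -- both for the four
#' physical traits and, unless `normalize_signal = FALSE`, for the eleven
#' signal features -- then the test subject is transformed with those
#' statistics (out-of-range values clip to `[0, 1]`). Ties in the final
#' ordering break lexicographically by subject id.
#'
#' @param test_traits The test subject's [physical_traits()].
#' @param test_features The test subject's similarity-sample feature block
#'   (matrix, 11 columns, one row per repetition; typically one set).
#' @param crowd Named list: per crowd subject, a list with `traits` and
#'   `features` (same 11-column layout).
#' @param params A [similarity_params()].
#' @param test_id Optional id of the test subject; an error is raised if it
#'   appears among the crowd names (leakage guard).
#' @param normalize_signal Min-max normalize the signal features before the
#'   distance (default `TRUE`; set `FALSE` for the literal un-normalized
#'   reading).
#' @return Data frame sorted by decreasing `sim_total`: `other_subject`,
#'   `d_phy`, `d_sig`, `sim_phy`, `sim_sig`, `sim_total`.
#' @export
rank_crowd <- function(test_traits, test_features, crowd,
                       params = similarity_params(), test_id = NULL,
                       normalize_signal = TRUE) {
  if (!length(crowd)) stop("rank_crowd(): empty crowd", call. = FALSE)
  ids <- names(crowd)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("rank_crowd(): crowd must be a named list", call. = FALSE)
  }
  if (!is.null(test_id) && test_id %in% ids) {
    stop("rank_crowd(): test subject present in crowd (leakage)",
         call. = FALSE)
  }
  trait_mat <- t(vapply(crowd, function(m) as.numeric(m$traits), numeric(4)))
  tstats <- fit_minmax(trait_mat)
  trait_norm <- apply_minmax(trait_mat, tstats)
  test_trait_norm <- apply_minmax(as.numeric(test_traits), tstats)

  featblocks <- lapply(crowd, function(m) as.matrix(m$features))
  test_feat <- as.matrix(test_features)
  if (normalize_signal) {
    sstats <- fit_minmax(do.call(rbind, featblocks))
    featblocks <- lapply(featblocks, apply_minmax, stats = sstats)
    test_feat <- apply_minmax(test_feat, sstats)
    if (is.null(dim(test_feat))) test_feat <- matrix(test_feat, nrow = 1)
  }

  d_phy <- vapply(seq_along(crowd), function(i) {
    physical_distance(test_trait_norm, trait_norm[i, ])
  }, numeric(1))
  d_sig <- vapply(featblocks, signal_distance, fq = test_feat, numeric(1))
  sim_phy <- similarity_from_distance(d_phy, params$gamma)
  sim_sig <- similarity_from_distance(d_sig, params$gamma)
  out <- data.frame(other_subject = ids, d_phy = d_phy, d_sig = d_sig,
                    sim_phy = sim_phy, sim_sig = sim_sig,
                    sim_total = total_similarity(sim_phy, sim_sig, params),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$sim_total, out$other_subject), ]
  rownames(out) <- NULL
  out
}
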