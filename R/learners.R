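# Base learners for boosting, implemented in-package: a depth-limited
# CART-style tree that consumes case weights natively, and a one-hidden-
# layer backprop network trained on weight-resampled data. Both are
# deliberately small: boosting wants weak learners.

# ---- weighted decision tree -------------------------------------------

# y is integer 0/1 (1 = positive class); w non-negative case weights.
weighted_gini_split <- function(x, y, w, min_node) {
  ord <- order(x)
  xs <- x[ord]
  wp <- cumsum(w[ord] * y[ord])        # positive mass left of split
  wa <- cumsum(w[ord])                 # total mass left of split
  n <- length(xs)
  tp <- wp[n]
  ta <- wa[n]
  cut_ok <- which(diff(xs) > 0)        # split between i and i+1
  cut_ok <- cut_ok[cut_ok >= min_node & cut_ok <= n - min_node]
  if (!length(cut_ok)) return(NULL)
  wl <- wa[cut_ok]
  pl <- ifelse(wl > 0, wp[cut_ok] / wl, 0)  # zero-mass side: pure by fiat
  wr <- ta - wl
  pr <- ifelse(wr > 0, (tp - wp[cut_ok]) / wr, 0)
  imp <- wl * 2 * pl * (1 - pl) + wr * 2 * pr * (1 - pr)
  best <- which.min(imp)
  list(threshold = (xs[cut_ok[best]] + xs[cut_ok[best] + 1L]) / 2,
       impurity = imp[best])
}

fit_weighted_tree <- function(x, y, w, max_depth = 3L, min_node = 5L) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), length(w) == length(y))
  build <- function(idx, depth) {
    wi <- w[idx]
    yi <- y[idx]
    p1 <- if (sum(wi) > 0) sum(wi * yi) / sum(wi) else mean(yi)
    leaf <- list(leaf = TRUE, prob = p1,
                 class = as.integer(p1 > 0.5))
    if (depth >= max_depth || length(idx) < 2L * min_node ||
        p1 <= 0 || p1 >= 1) {
      return(leaf)
    }
    node_imp <- sum(wi) * 2 * p1 * (1 - p1)
    best <- NULL
    for (j in seq_len(ncol(x))) {
      sp <- weighted_gini_split(x[idx, j], yi, wi, min_node)
      if (!is.null(sp) && sp$impurity < (best$impurity %||% node_imp) - 1e-12) {
        best <- list(feature = j, threshold = sp$threshold,
                     impurity = sp$impurity)
      }
    }
    if (is.null(best)) return(leaf)
    go_left <- x[idx, best$feature] <= best$threshold
    list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
         left = build(idx[go_left], depth + 1L),
         right = build(idx[!go_left], depth + 1L))
  }
  structure(list(root = build(seq_len(nrow(x)), 0L), p = ncol(x)),
            class = "cf_tree")
}

predict_tree <- function(tree, x) {
  x <- as.matrix(x)
  out <- integer(nrow(x))
  walk <- function(node, idx) {
    if (!length(idx)) return()
    if (node$leaf) {
      out[idx] <<- node$class
      return()
    }
    go_left <- x[idx, node$feature] <= node$threshold
    walk(node$left, idx[go_left])
    walk(node$right, idx[!go_left])
  }
  walk(tree$root, seq_len(nrow(x)))
  out
}

# ---- one-hidden-layer neural net --------------------------------------

# Binary cross-entropy MLP: tanh hidden layer, sigmoid output, full-batch
# gradient descent with momentum. Inputs are standardized internally.
fit_mlp <- function(x, y, hidden = 16L, epochs = 200L, lr = 0.05,
                    momentum = 0.9, l2 = 1e-4) {
  x <- as.matrix(x)
  n <- nrow(x)
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  xs <- sweep(sweep(x, 2, center, "-"), 2, scale, "/")
  p <- ncol(xs)
  w1 <- matrix(stats::rnorm(p * hidden, sd = 1 / sqrt(p)), p, hidden)
  b1 <- numeric(hidden)
  w2 <- stats::rnorm(hidden, sd = 1 / sqrt(hidden))
  b2 <- 0
  v1 <- matrix(0, p, hidden); vb1 <- numeric(hidden)
  v2 <- numeric(hidden); vb2 <- 0
  for (e in seq_len(epochs)) {
    h <- tanh(xs %*% w1 + matrix(b1, n, hidden, byrow = TRUE))
    z <- drop(h %*% w2) + b2
    prob <- 1 / (1 + exp(-z))
    delta <- (prob - y) / n                     # d loss / d z
    g2 <- drop(crossprod(h, delta)) + l2 * w2
    gb2 <- sum(delta)
    dh <- outer(delta, w2) * (1 - h^2)
    g1 <- crossprod(xs, dh) + l2 * w1
    gb1 <- colSums(dh)
    v2 <- momentum * v2 - lr * g2;   w2 <- w2 + v2
    vb2 <- momentum * vb2 - lr * gb2; b2 <- b2 + vb2
    v1 <- momentum * v1 - lr * g1;   w1 <- w1 + v1
    vb1 <- momentum * vb1 - lr * gb1; b1 <- b1 + vb1
  }
  structure(list(w1 = w1, b1 = b1, w2 = w2, b2 = b2,
                 center = center, scale = scale),
            class = "cf_mlp")
}

predict_mlp <- function(model, x) {
  x <- as.matrix(x)
  xs <- sweep(sweep(x, 2, model$center, "-"), 2, model$scale, "/")
  h <- tanh(xs %*% model$w1 +
              matrix(model$b1, nrow(xs), length(model$b1), byrow = TRUE))
  z <- drop(h %*% model$w2) + model$b2
  as.integer(1 / (1 + exp(-z)) > 0.5)
}
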