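# Small random-forest classifier for genotype imputation.
#
# Predictors are allele doses (values 0/2 after mode-fill), the response a
# two-class dose. Trees are grown CART-style on bootstrap samples with a
# random feature subset drawn at every split (Gini impurity); with binary
# predictors every split threshold is 1, so split search reduces to
# scoring candidate features. Prediction is the majority vote over trees,
# ties broken toward `tie_class`.

.gini_gain <- function(yl, nl, yr, nr) {
  # yl/yr: count of class-1 in left/right; nl/nr: node sizes
  pl <- yl / nl; pr <- yr / nr
  wl <- nl / (nl + nr)
  -(wl * 2 * pl * (1 - pl) + (1 - wl) * 2 * pr * (1 - pr))
}

.grow_tree <- function(X, y, mtry, min_node = 2L, max_depth = 12L) {
  # X: n x p matrix with values in {0, 2}; y: integer 0/1 class
  build <- function(idx, depth) {
    n <- length(idx)
    ones <- sum(y[idx])
    if (ones == 0L || ones == n || n < min_node || depth >= max_depth)
      return(list(leaf = TRUE, class = as.integer(ones * 2L >= n)))
    feats <- sample.int(ncol(X), min(mtry, ncol(X)))
    best <- NULL; best_gain <- -Inf
    for (f in feats) {
      left <- X[idx, f] < 1
      nl <- sum(left)
      if (nl == 0L || nl == n) next
      g <- .gini_gain(sum(y[idx][left]), nl, ones - sum(y[idx][left]), n - nl)
      if (g > best_gain) { best_gain <- g; best <- f }
    }
    if (is.null(best))
      return(list(leaf = TRUE, class = as.integer(ones * 2L >= n)))
    left <- X[idx, best] < 1
    list(leaf = FALSE, feature = best,
         l = build(idx[left], depth + 1L),
         r = build(idx[!left], depth + 1L))
  }
  build(seq_len(nrow(X)), 0L)
}

.predict_tree <- function(tree, X) {
  out <- integer(nrow(X))
  walk <- function(node, idx) {
    if (!length(idx)) return()
    if (node$leaf) { out[idx] <<- node$class; return() }
    left <- X[idx, node$feature] < 1
    walk(node$l, idx[left])
    walk(node$r, idx[!left])
  }
  walk(tree, seq_len(nrow(X)))
  out
}

# Fit a forest on (X_train, y01) and return class-1 vote fractions on X_test.
.rf_votes <- function(X_train, y01, X_test, n_trees, mtry = NULL) {
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X_train))))
  votes <- numeric(nrow(X_test))
  n <- nrow(X_train)
  for (b in seq_len(n_trees)) {
    boot <- sample.int(n, n, replace = TRUE)
    tree <- .grow_tree(X_train[boot, , drop = FALSE], y01[boot], mtry)
    votes <- votes + .predict_tree(tree, X_test)
  }
  votes / n_trees
}
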