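#' Population structure by discriminant analysis of principal components
#'
#' Centres the dose matrix, retains at most `floor(N/3)` principal
#' components (the DAPC stability rule; 56 PCs for a 169-line panel),
#' clusters lines by k-means on the retained PC scores (fixed `n_groups`,
#' or BIC-selected over k = 1..10 when `"auto"`), and derives membership
#' probabilities Q from a linear discriminant analysis on the retained
#' PCs. Q rows sum to 1.
#'
#' @param g imputed [genotype_matrix()]
#' @param n_groups number of subpopulations, or `"auto"` for BIC selection
#' @param seed integer seed (k-means initialization)
#' @param n_pcs PCs to retain; default, and upper bound, is `floor(N/3)`
#' @return list of class `structure_result`: `n_pcs`, `groups` (named
#'   integer vector), `Q` (lines x groups membership probabilities),
#'   `var_explained`, `k`, `bic` (when auto)
#' @export
dapc_structure <- function(g, n_groups = 4, seed = 1, n_pcs = NULL) {
  d <- g$dose
  if (anyNA(d)) stop("missing calls: impute before structure analysis")
  n <- nrow(d)
  auto <- identical(n_groups, "auto")
  if (!auto && n_groups > n) stop("n_groups exceeds the number of lines")
  max_pcs <- max(1L, floor(n / 3))
  pca <- stats::prcomp(d, center = TRUE, scale. = FALSE)
  avail <- sum(pca$sdev > 1e-10)
  keep <- min(if (is.null(n_pcs)) max_pcs else n_pcs, max_pcs, avail)
  scores <- pca$x[, seq_len(keep), drop = FALSE]
  var_explained <- sum(pca$sdev[seq_len(keep)]^2) / sum(pca$sdev^2)

  set.seed(seed)
  bic <- NULL
  if (auto) {
    # conservative model-based selection: equal-variance diagonal Gaussian
    # mixture on the leading standardized PCs, scored by ICL (BIC plus the
    # assignment entropy), so splitting unimodal noise is never rewarded
    q <- min(3L, keep)
    lead <- scores[, seq_len(q), drop = FALSE]
    lead <- sweep(lead, 2, apply(lead, 2, stats::sd), "/")
    ks <- seq_len(min(10L, n - 1L))
    bic <- vapply(ks, function(k) .gmm_icl(lead, k), numeric(1))
    k <- ks[which.min(bic)]
  } else k <- as.integer(n_groups)

  if (k == 1) {
    groups <- stats::setNames(rep(1L, n), rownames(d))
    Q <- matrix(1, n, 1, dimnames = list(rownames(d), "1"))
  } else {
    km <- stats::kmeans(scores, k, nstart = 10, iter.max = 50)
    lda <- MASS::lda(scores, grouping = factor(km$cluster))
    post <- stats::predict(lda, scores)$posterior
    groups <- stats::setNames(max.col(post, ties.method = "first"),
                              rownames(d))
    Q <- post
    rownames(Q) <- rownames(d)
  }
  structure(list(n_pcs = keep, groups = groups, Q = Q,
                 var_explained = var_explained, k = k, bic = bic),
            class = "structure_result")
}

#' @export
print.structure_result <- function(x, ...) {
  cat(sprintf("structure_result: %d group(s), %d PCs retained (%.1f%% variance)\n",
              x$k, x$n_pcs, 100 * x$var_explained))
  invisible(x)
}

# ICL of an equal-variance (per axis) diagonal Gaussian mixture fitted by
# EM from a k-means start. Returns -2 loglik + npar log(n) + 2 * entropy.
.gmm_icl <- function(X, k, n_iter = 80L) {
  n <- nrow(X); q <- ncol(X)
  dens <- function(mu_j, v) {
    rowSums(stats::dnorm(X, matrix(rep(mu_j, each = n), n, q),
                         matrix(rep(sqrt(v), each = n), n, q), log = TRUE))
  }
  if (k == 1) {
    mu <- colMeans(X)
    v <- pmax(colMeans(sweep(X, 2, mu)^2), 1e-4)
    return(-2 * sum(dens(mu, v)) + 2 * q * log(n))
  }
  km <- stats::kmeans(X, k, nstart = 10, iter.max = 50)
  mu <- km$centers
  w <- pmax(km$size / n, 1e-8)
  v <- pmax(colSums((X - km$centers[km$cluster, , drop = FALSE])^2) / n, 1e-4)
  r <- NULL
  for (it in seq_len(n_iter)) {
    logd <- vapply(seq_len(k), function(j) log(w[j]) + dens(mu[j, ], v),
                   numeric(n))
    mx <- apply(logd, 1, max)
    r <- exp(logd - mx); r <- r / rowSums(r)
    nk <- pmax(colSums(r), 1e-8)
    w <- nk / n
    for (j in seq_len(k)) mu[j, ] <- colSums(r[, j] * X) / nk[j]
    v <- pmax(Reduce(`+`, lapply(seq_len(k), function(j)
      colSums(r[, j] * sweep(X, 2, mu[j, ])^2))) / n, 1e-4)
  }
  logd <- vapply(seq_len(k), function(j) log(w[j]) + dens(mu[j, ], v),
                 numeric(n))
  mx <- apply(logd, 1, max)
  ll <- sum(mx + log(rowSums(exp(logd - mx))))
  ent <- -sum(r[r > 1e-12] * log(r[r > 1e-12]))
  npar <- k * q + q + (k - 1)
  -2 * ll + npar * log(n) + 2 * ent
}

#' Kinship matrix for an inbred panel
#'
#' `"scaled-ibs"` (default, TASSEL-style): the pairwise allele-sharing
#' proportion `s`, rescaled as `(s - min(s)) / (1 - min(s))` so the least
#' related pair sits at 0. `"centered"` (VanRaden): cross-product of
#' centred doses scaled by `2 * sum(p * (1 - p))`. Both are symmetric;
#' the method is recorded in the `"method"` attribute.
#'
#' @param g imputed [genotype_matrix()] with at least two lines
#' @param method `"scaled-ibs"` or `"centered"`
#' @return symmetric lines x lines matrix of class `kinship_matrix`
#' @export
kinship_matrix <- function(g, method = c("scaled-ibs", "centered")) {
  method <- match.arg(method)
  d <- g$dose
  if (anyNA(d)) stop("missing calls: impute before kinship")
  if (nrow(d) < 2) stop("kinship needs at least two lines")
  if (any(d == 1)) stop("heterozygous calls present: impute first")
  m <- ncol(d)
  if (method == "scaled-ibs") {
    a <- d / 2                      # 0/1 for inbred homozygotes
    # mean |a_i - a_j| via the binary identity |x-y| = x + y - 2xy
    cross <- tcrossprod(a) / m
    rm_ <- rowMeans(a)
    s <- 1 - (outer(rm_, rm_, "+") - 2 * cross)
    K <- (s - min(s)) / (1 - min(s))
  } else {
    p <- colMeans(d) / 2
    W <- sweep(d, 2, 2 * p)
    denom <- 2 * sum(p * (1 - p))
    if (denom <= 0) stop("all markers monomorphic: kinship undefined")
    K <- tcrossprod(W) / denom
  }
  K <- (K + t(K)) / 2
  dimnames(K) <- list(rownames(d), rownames(d))
  attr(K, "method") <- method
  class(K) <- c("kinship_matrix", class(K))
  K
}
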