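# EMMA-style REML for the single-random-effect mixed model
#   y = X b + u + e,  Var(u) = sg * K,  Var(e) = se * I.
#
# The restricted likelihood is profiled over delta = se / sg using the
# spectral decomposition of S K S (S the projection off the fixed
# effects), maximized on a log-delta grid refined by golden-section
# search. With the components in hand, the model is whitened through the
# eigendecomposition of K so every downstream test is ordinary least
# squares on transformed data.

.check_psd_eigen <- function(K) {
  e <- eigen(K, symmetric = TRUE)
  tol <- 1e-8 * max(abs(e$values), 1)
  if (min(e$values) < -sqrt(tol) * 10)
    stop("kinship matrix is not positive semi-definite (min eigenvalue ",
         format(min(e$values)), ")")
  e$values <- pmax(e$values, 0)
  e
}

.reml_emma <- function(y, X, K) {
  n <- length(y)
  q <- qr(X)$rank
  XtXi <- solve(crossprod(X) + diag(1e-12, ncol(X)))
  S <- diag(n) - X %*% XtXi %*% t(X)
  A <- S %*% K %*% S
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  lam <- pmax(e$values[seq_len(n - q)], 0)
  W <- e$vectors[, seq_len(n - q), drop = FALSE]
  eta <- as.numeric(crossprod(W, y))
  nq <- n - q
  ll <- function(ld) {
    dl <- lam + exp(ld)
    0.5 * (nq * (log(nq / (2 * pi)) - 1 - log(sum(eta^2 / dl))) -
             sum(log(dl)))
  }
  grid <- seq(-10, 10, length.out = 81)
  vals <- vapply(grid, ll, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(ll, c(lo, hi), maximum = TRUE, tol = 1e-8)
  delta <- exp(opt$maximum)
  sg <- sum(eta^2 / (lam + delta)) / nq
  list(sigma_g = sg, sigma_e = delta * sg, delta = delta,
       loglik = opt$objective)
}

# n x n whitening transform T with T V T' = I, V = sg K + se I
.whitener <- function(K_eigen, sigma_g, sigma_e) {
  d <- sigma_g * K_eigen$values + sigma_e
  if (any(d <= 0)) stop("degenerate variance: V is singular")
  K_eigen$vectors %*% (t(K_eigen$vectors) / sqrt(d))
}

#' Mixed-model variance components under the null model
#'
#' Estimates the polygenic and residual variance of
#' `y = X b + u + e`, `Var(u) = sigma_g K`, `Var(e) = sigma_e I`, by
#' EMMA-style REML. Used directly for P3D scans ("population parameters
#' previously determined"), where the components estimated once without
#' any locus term are reused for every locus.
#'
#' @param y numeric response
#' @param X fixed-effect design matrix (intercept and covariates)
#' @param K kinship matrix aligned with `y`
#' @return list with `sigma_g`, `sigma_e`, `delta` (= sigma_e/sigma_g)
#'   and the restricted log-likelihood
#' @export
mlm_null_reml <- function(y, X, K) .reml_emma(y, X, K)
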