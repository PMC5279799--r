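#' Adaptive step-up false-discovery-rate adjustment
#'
#' Storey-Taylor-Siegmund adaptive procedure: the null proportion is
#' estimated as `pi0 = (#\{p > lambda\} + 1) / (m * (1 - lambda))`,
#' capped at 1, with `lambda = alpha / (1 + alpha)` by default; adjusted
#' p-values are the Benjamini-Hochberg step-up values with `m` replaced
#' by `m * pi0`. A locus is significant when its adjusted p-value is
#' below `alpha`.
#'
#' @param pvals p-values in (0, 1]
#' @param alpha FDR level (default 0.05)
#' @param lambda tuning constant for the pi0 estimate
#' @return list with `p_adj` (same order as input), `significant`
#'   (logical), and `pi0`
#' @export
adjust_fdr <- function(pvals, alpha = 0.05, lambda = alpha / (1 + alpha)) {
  if (!length(pvals)) stop("empty p-value vector")
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1))
    stop("p-values must lie in (0, 1]")
  m <- length(pvals)
  pi0 <- min(1, (sum(pvals > lambda) + 1) / (m * (1 - lambda)))
  o <- order(pvals)
  ranked <- pvals[o] * m * pi0 / seq_len(m)
  adj <- rev(cummin(rev(ranked)))      # enforce step-up monotonicity
  adj <- pmin(adj, 1)
  p_adj <- numeric(m)
  p_adj[o] <- adj
  list(p_adj = p_adj, significant = p_adj < alpha, pi0 = pi0)
}

#' Quantile-quantile points for p-value diagnostics
#'
#' @param pvals non-empty p-value vector
#' @return data frame with `expected` and `observed` -log10 p-values,
#'   sorted so the most significant point comes last
#' @export
qq_points <- function(pvals) {
  if (!length(pvals)) stop("empty p-value vector")
  m <- length(pvals)
  data.frame(expected = -log10(((m:1) - 0.5) / m),
             observed = -log10(sort(pvals, decreasing = TRUE)))
}
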