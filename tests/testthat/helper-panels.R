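# Shared builders and independent oracles for the test suite.

# genotype matrix from a bare dose matrix, auto-naming lines/markers
toy_genotypes <- function(dose, alleles = NULL) {
  if (is.null(rownames(dose)))
    rownames(dose) <- sprintf("L%02d", seq_len(nrow(dose)))
  if (is.null(colnames(dose)))
    colnames(dose) <- sprintf("M%02d", seq_len(ncol(dose)))
  genotype_matrix(dose, alleles)
}

toy_map <- function(markers, chrom, pos) {
  genetic_map(data.frame(marker = markers, chrom = chrom, pos = pos,
                         stringsAsFactors = FALSE))
}

# small structured panel used across tests
quick_panel <- function(seed, n_lines = 80, markers = 30,
                        chroms = setNames(rep(60, 4), c("1A", "1B", "2A", "2B")),
                        ld_rho = 0.3, fst = 0.2, missing_rate = 0,
                        qtl = list(), h2 = 0.4, n_subpops = 4) {
  simulate_panel(sim_config(
    n_lines = n_lines, n_subpops = n_subpops, fst = fst,
    chromosomes = chroms, markers_per_chrom = markers, ld_rho = ld_rho,
    missing_rate = missing_rate, qtl_spec = qtl, h2_polygenic = h2,
    noise_sd = 1, seed = seed))
}

# Weir-Cockerham theta for haploid samples (inbred lines), ratio of sums
wc_fst <- function(dose, pops) {
  a_sum <- 0; ab_sum <- 0
  r <- length(unique(pops))
  for (j in seq_len(ncol(dose))) {
    x <- dose[, j] / 2
    ni <- tapply(x, pops, length)
    pi <- tapply(x, pops, mean)
    nbar <- mean(ni)
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    pbar <- sum(ni * pi) / (r * nbar)
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    if (pbar <= 0 || pbar >= 1) next
    a <- (nbar / nc) *
      (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r)
    a_sum <- a_sum + a
    ab_sum <- ab_sum + a + b
  }
  a_sum / ab_sum
}

# closed-form GLS F-test of added columns L given covariates X, known V
gls_f_oracle <- function(y, X, L, V) {
  Vi <- solve(V)
  rss <- function(M) {
    b <- solve(t(M) %*% Vi %*% M, t(M) %*% Vi %*% y)
    r <- y - M %*% b
    as.numeric(t(r) %*% Vi %*% r)
  }
  r0 <- rss(X); r1 <- rss(cbind(X, L))
  df1 <- qr(cbind(X, L))$rank - qr(X)$rank
  df2 <- length(y) - qr(cbind(X, L))$rank
  Fs <- ((r0 - r1) / df1) / (r1 / df2)
  list(F = Fs, p = pf(Fs, df1, df2, lower.tail = FALSE))
}
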