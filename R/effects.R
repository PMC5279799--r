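#' Allelic effect of a carrier subset
#'
#' The effect of an allele is the mean trait value of the lines carrying
#' it minus the mean of the entire panel.
#'
#' @param y named trait vector
#' @param carriers line ids or logical index over `y`
#' @return effect in trait units
#' @export
allelic_effect <- function(y, carriers) {
  sel <- if (is.logical(carriers)) carriers else names(y) %in% carriers
  if (!any(sel)) stop("empty carrier set")
  mean(y[sel]) - mean(y)
}

#' Percent increase of haplotype over SNP statistics
#'
#' `IVE = 100 * (R2_hap - R2_snp) / R2_snp` (increase in variance
#' explained); `IAE = 100 * (|effect_hap| - |effect_snp|) / |effect_snp|`
#' (increase in allelic effect).
#'
#' @param r2_hap,r2_snp variance explained (%) by the haplotype locus and
#'   its matched SNP
#' @param effect_hap,effect_snp allelic effects (trait units)
#' @return named vector `c(IVE = , IAE = )`
#' @export
ive_iae <- function(r2_hap, r2_snp, effect_hap, effect_snp) {
  c(IVE = 100 * (r2_hap - r2_snp) / r2_snp,
    IAE = 100 * (abs(effect_hap) - abs(effect_snp)) / abs(effect_snp))
}

#' Match significant haplotype loci to SNPs and quantify the gain
#'
#' Every significant haplotype locus is paired with the significant SNP
#' whose map position falls inside the block interval; when several
#' qualify, the SNP with the smallest p-value is taken. IVE and IAE are
#' computed per matched pair and averaged. Unmatched haplotype loci keep
#' empty SNP fields.
#'
#' @param hap_results an `assoc_result` from a haplotype scan
#' @param snp_results an `assoc_result` from a single-SNP scan of the
#'   same trait on the same panel
#' @param blocks the `haplotype_block_set` behind `hap_results`
#' @param map a [genetic_map()] giving SNP positions
#' @param alpha significance level on adjusted p-values
#' @return data frame of class `comparison_table`; attribute `means`
#'   holds the average IVE and IAE over matched rows
#' @export
compare_loci <- function(hap_results, snp_results, blocks, map,
                         alpha = 0.05) {
  hap <- hap_results[hap_results$type == "hap" &
                       hap_results$p_adj < alpha, , drop = FALSE]
  snp <- snp_results[snp_results$type == "snp" &
                       snp_results$p_adj < alpha, , drop = FALSE]
  snp$pos <- map$pos[match(snp$locus, map$marker)]
  snp$chrom_map <- map$chrom[match(snp$locus, map$marker)]
  rows <- lapply(seq_len(nrow(hap)), function(i) {
    h <- hap[i, ]
    bi <- blocks$blocks[blocks$blocks$locus == h$locus, , drop = FALSE]
    cand <- snp[!is.na(snp$pos) & snp$chrom_map == bi$chrom &
                  snp$pos >= bi$start & snp$pos <= bi$end, , drop = FALSE]
    out <- data.frame(locus = h$locus, chrom = h$chrom,
                      start = h$start, end = h$end, nbM = h$nbM,
                      hap_p = h$p, hap_p_adj = h$p_adj,
                      hap_r2 = h$r2_pct, hap_effect = h$effect,
                      snp = NA_character_, snp_pos = NA_real_,
                      snp_p = NA_real_, snp_r2 = NA_real_,
                      snp_effect = NA_real_, IVE = NA_real_,
                      IAE = NA_real_, stringsAsFactors = FALSE)
    if (nrow(cand)) {
      s <- cand[which.min(cand$p), ]
      gain <- ive_iae(h$r2_pct, s$r2_pct, h$effect, s$effect)
      out$snp <- s$locus; out$snp_pos <- s$pos
      out$snp_p <- s$p; out$snp_r2 <- s$r2_pct; out$snp_effect <- s$effect
      out$IVE <- gain[["IVE"]]; out$IAE <- gain[["IAE"]]
    }
    out
  })
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(locus = character(0), chrom = character(0),
               start = numeric(0), end = numeric(0), nbM = integer(0),
               hap_p = numeric(0), hap_p_adj = numeric(0),
               hap_r2 = numeric(0), hap_effect = numeric(0),
               snp = character(0), snp_pos = numeric(0),
               snp_p = numeric(0), snp_r2 = numeric(0),
               snp_effect = numeric(0), IVE = numeric(0),
               IAE = numeric(0), stringsAsFactors = FALSE)
  matched <- !is.na(res$IVE)
  attr(res, "means") <- c(
    IVE = if (any(matched)) mean(res$IVE[matched]) else NA_real_,
    IAE = if (any(matched)) mean(res$IAE[matched]) else NA_real_)
  class(res) <- c("comparison_table", "data.frame")
  res
}

#' Colour loss as residual pigment change during processing
#'
#' Regresses pasta b* on semolina b* by ordinary least squares (with
#' intercept) and returns the residuals, observed minus predicted, as
#' the colour-loss trait. Residuals average zero; positive values mean
#' less pigment loss than the population average.
#'
#' @param pasta_b,semolina_b named trait vectors (aligned by line id)
#' @return named residual vector over the common lines
#' @export
colour_loss_residuals <- function(pasta_b, semolina_b) {
  common <- intersect(names(pasta_b)[!is.na(pasta_b)],
                      names(semolina_b)[!is.na(semolina_b)])
  if (length(common) < 3) stop("need at least 3 common phenotyped lines")
  x <- semolina_b[common]; y <- pasta_b[common]
  if (stats::sd(x) == 0) stop("semolina b* has zero variance")
  stats::residuals(stats::lm(y ~ x))
}

#' Pairwise Pearson correlations among traits
#'
#' @param pheno a [phenotype_table()]
#' @return list with `r` (correlation matrix), `p` (two-sided p-values)
#'   and `n` (complete pairs); constant traits give NA with a warning
#' @export
trait_correlations <- function(pheno) {
  traits <- names(pheno)[-1]
  k <- length(traits)
  r <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    x <- pheno[[traits[i]]]; y <- pheno[[traits[j]]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3) next
    nmat[i, j] <- nmat[j, i] <- sum(ok)
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      warning("constant trait in pair ", traits[i], " / ", traits[j])
      next
    }
    ct <- stats::cor.test(x[ok], y[ok])
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  list(r = r, p = p, n = nmat)
}

#' LD between association signals and candidate-gene markers
#'
#' @param g imputed [genotype_matrix()]
#' @param signal_markers,gene_markers marker ids present in `g`
#' @return data frame with one row per (signal, gene) pair and its
#'   r-squared
#' @export
candidate_gene_ld <- function(g, signal_markers, gene_markers) {
  missing_ids <- setdiff(c(signal_markers, gene_markers), marker_ids(g))
  if (length(missing_ids))
    stop("unknown marker id(s): ", paste(missing_ids, collapse = ", "))
  grid <- expand.grid(signal = signal_markers, gene = gene_markers,
                      stringsAsFactors = FALSE)
  grid$r2 <- vapply(seq_len(nrow(grid)), function(i)
    pairwise_r2(g$dose[, grid$signal[i]], g$dose[, grid$gene[i]]),
    numeric(1))
  grid
}
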