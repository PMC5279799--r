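#' Marker quality-control filter
#'
#' Removes markers with too many missing calls or too low a minor-allele
#' frequency. MAF is computed on non-missing calls only, before any
#' imputation; heterozygous calls contribute one copy of each allele.
#' Filtering is idempotent and invariant to allele-label swaps.
#'
#' @param g a [genotype_matrix()]
#' @param max_missing maximum tolerated missing fraction per marker
#'   (default 0.25; markers *above* the threshold are removed)
#' @param min_maf minimum minor-allele frequency (default 0.05; markers
#'   *below* the threshold are removed)
#' @return list with `genotypes` (filtered) and `report` (a `qc_report`:
#'   counts of removals per rule and per-marker statistics)
#' @export
qc_filter <- function(g, max_missing = 0.25, min_maf = 0.05) {
  if (max_missing < 0 || max_missing > 1 || min_maf < 0 || min_maf > 1)
    stop("thresholds must lie in [0, 1]")
  d <- g$dose
  miss <- colMeans(is.na(d))
  nobs <- colSums(!is.na(d))
  f_alt <- colSums(d, na.rm = TRUE) / (2 * pmax(nobs, 1L))
  maf <- pmin(f_alt, 1 - f_alt)
  maf[nobs == 0] <- 0
  fail_missing <- miss > max_missing
  fail_maf <- maf < min_maf
  keep <- !fail_missing & !fail_maf
  report <- structure(list(
    n_input = ncol(d),
    n_removed_missing = sum(fail_missing),
    n_removed_maf = sum(fail_maf),
    n_retained = sum(keep),
    max_missing = max_missing,
    min_maf = min_maf,
    maf_computed = "before imputation, non-missing calls only",
    per_marker = data.frame(marker = colnames(d), missing = miss, maf = maf,
                            retained = keep, row.names = NULL)
  ), class = "qc_report")
  if (!any(keep))
    warning("no markers survive QC filtering; returning an empty matrix")
  list(genotypes = subset_genotypes(g, markers = which(keep)),
       report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0("qc_report: %d markers in; %d removed for missingness",
                     " (> %.2f), %d for MAF (< %.2f); %d retained\n"),
              x$n_input, x$n_removed_missing, x$max_missing,
              x$n_removed_maf, x$min_maf, x$n_retained))
  invisible(x)
}
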