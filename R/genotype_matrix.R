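#' Construct a genotype matrix for an inbred panel
#'
#' The central genotype container: a lines x markers allele-dose matrix.
#' Doses are coded 0 and 2 for the two homozygotes, 1 for a heterozygous
#' call (tolerated on input, treated as missing by LD and haplotype
#' computations), and `NA` for missing. Row names are line identifiers,
#' column names are marker identifiers; both must be unique.
#'
#' @param dose numeric matrix with values in \{0, 1, 2, NA\}; rownames are
#'   line ids, colnames are marker ids.
#' @param alleles optional data frame with columns `marker`, `a0`, `a1`
#'   giving the single-character base for dose 0 and dose 2 at each marker.
#'   Used when writing HapMap-style or VCF output and when spelling
#'   haplotype alleles; when absent, alleles are spelled "0"/"1".
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dose, alleles = NULL) {
  if (!is.matrix(dose) || !is.numeric(dose))
    stop("`dose` must be a numeric matrix")
  if (is.null(rownames(dose)) || is.null(colnames(dose)))
    stop("`dose` must carry line ids (rownames) and marker ids (colnames)")
  if (anyDuplicated(rownames(dose)))
    stop("duplicate line ids in genotype matrix")
  if (anyDuplicated(colnames(dose)))
    stop("duplicate marker ids in genotype matrix")
  vals <- dose[!is.na(dose)]
  if (length(vals) && !all(vals %in% c(0, 1, 2)))
    stop("allele doses must be 0, 1, 2 or NA")
  if (!is.null(alleles)) {
    if (!all(c("marker", "a0", "a1") %in% names(alleles)))
      stop("`alleles` needs columns marker, a0, a1")
    if (!all(colnames(dose) %in% alleles$marker))
      stop("`alleles` must cover every marker")
    alleles <- alleles[match(colnames(dose), alleles$marker), , drop = FALSE]
    rownames(alleles) <- NULL
  }
  structure(list(dose = dose, alleles = alleles), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  d <- x$dose
  nm <- sum(is.na(d))
  cat(sprintf("genotype_matrix: %d lines x %d markers (%.1f%% missing)\n",
              nrow(d), ncol(d), 100 * nm / length(d)))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param g a `genotype_matrix`
#' @export
n_lines <- function(g) nrow(g$dose)

#' @rdname genotype_matrix
#' @export
n_markers <- function(g) ncol(g$dose)

#' @rdname genotype_matrix
#' @export
line_ids <- function(g) rownames(g$dose)

#' @rdname genotype_matrix
#' @export
marker_ids <- function(g) colnames(g$dose)

#' Subset a genotype matrix by markers and/or lines
#'
#' @param g a `genotype_matrix`
#' @param markers marker ids or logical/integer index over columns
#' @param lines line ids or index over rows
#' @return a `genotype_matrix`
#' @export
subset_genotypes <- function(g, markers = NULL, lines = NULL) {
  d <- g$dose
  if (!is.null(markers)) d <- d[, markers, drop = FALSE]
  if (!is.null(lines)) d <- d[lines, , drop = FALSE]
  al <- g$alleles
  if (!is.null(al)) al <- al[al$marker %in% colnames(d), , drop = FALSE]
  genotype_matrix(d, al)
}

# internal: replace the dose matrix, keeping allele spellings aligned
.with_dose <- function(g, dose) genotype_matrix(dose, g$alleles)
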