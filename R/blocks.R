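#' Collapse duplicate SNP columns within chromosomes
#'
#' Markers on the same chromosome whose dose vectors are identical across
#' all lines (directly or after a global allele-label flip) are
#' represented by a single marker: the member with the smallest map
#' position, ties broken by lexicographic marker id. Identical columns on
#' different chromosomes are kept.
#'
#' @param g imputed [genotype_matrix()] (no missing calls)
#' @param map a [genetic_map()]
#' @return list with `genotypes` (deduplicated) and `report` (a
#'   `dedup_report`: list mapping representative -> member ids)
#' @export
deduplicate <- function(g, map) {
  d <- g$dose
  if (anyNA(d)) stop("missing calls: impute before deduplication")
  map <- map[match(colnames(d), map$marker), , drop = FALSE]
  if (anyNA(map$marker)) stop("every marker must be on the map")
  keys <- vapply(seq_len(ncol(d)), function(j) {
    s1 <- paste(d[, j], collapse = ",")
    s2 <- paste(2 - d[, j], collapse = ",")
    if (s1 < s2) s1 else s2
  }, character(1))
  grp <- paste(map$chrom, keys, sep = "|")
  groups <- split(seq_len(ncol(d)), grp)
  reps <- vapply(groups, function(idx) {
    idx[order(map$pos[idx], map$marker[idx])][1]
  }, integer(1))
  report <- lapply(groups, function(idx) map$marker[sort(idx)])
  names(report) <- map$marker[reps]
  keep <- sort(unname(reps))
  structure_report <- structure(list(groups = report,
                                     n_input = ncol(d),
                                     n_retained = length(keep)),
                                class = "dedup_report")
  list(genotypes = subset_genotypes(g, markers = keep),
       report = structure_report)
}

#' @export
print.dedup_report <- function(x, ...) {
  cat(sprintf("dedup_report: %d markers in, %d retained (%d collapsed)\n",
              x$n_input, x$n_retained, x$n_input - x$n_retained))
  invisible(x)
}

#' Partition mapped markers into LD-window haplotype blocks
#'
#' Each chromosome is divided into consecutive half-open windows
#' `[s, s+w), [s+w, s+2w), ...` anchored at the chromosome's first marker
#' position `s`. Windows holding at least two markers become haplotype
#' blocks, named `hap_<chrom>_<index>` with the index counting emitted
#' blocks along the chromosome; singleton windows are recorded separately
#' and analysed as plain SNPs. Block intervals report the member-marker
#' span (min-max cM), as printed in association tables.
#'
#' @param map a [genetic_map()] of the (deduplicated) markers to use
#' @param window_cM window width in cM, typically the fitted genome-wide
#'   LD decay distance
#' @return a `haplotype_block_set` (structure only; call
#'   [call_block_alleles()] to attach per-line alleles)
#' @export
build_blocks <- function(map, window_cM) {
  if (!is.numeric(window_cM) || window_cM <= 0)
    stop("window_cM must be positive")
  blocks <- list(); members <- list(); singles <- list()
  for (chrom in unique(map$chrom)) {
    sub <- map[map$chrom == chrom, , drop = FALSE]
    sub <- sub[order(sub$pos, sub$marker), , drop = FALSE]
    s <- sub$pos[1]
    win <- floor((sub$pos - s) / window_cM)
    idx <- 0L
    for (w in sort(unique(win))) {
      mem <- sub[win == w, , drop = FALSE]
      if (nrow(mem) >= 2) {
        idx <- idx + 1L
        locus <- sprintf("hap_%s_%d", chrom, idx)
        blocks[[locus]] <- data.frame(
          locus = locus, chrom = chrom,
          start = min(mem$pos), end = max(mem$pos),
          win_start = s + w * window_cM, win_end = s + (w + 1) * window_cM,
          n_snps = nrow(mem), stringsAsFactors = FALSE)
        members[[locus]] <- mem$marker
      } else {
        singles[[length(singles) + 1L]] <- mem
      }
    }
  }
  structure(list(
    blocks = if (length(blocks)) do.call(rbind, c(blocks, make.row.names = FALSE))
             else data.frame(),
    members = members,
    singletons = if (length(singles)) do.call(rbind, singles)[, c("marker", "chrom", "pos")]
                 else data.frame(marker = character(0)),
    window_cM = window_cM,
    calls = NULL, freqs = NULL, dropped = NULL
  ), class = "haplotype_block_set")
}

#' Call multi-allelic haplotype alleles per line
#'
#' Each line's allele at a block is the ordered concatenation of its
#' member-SNP alleles (base letters when the genotype matrix carries
#' allele spellings, otherwise 0/1 allele indices). Alleles with
#' frequency below `min_haf` are pooled into a single `"rare"` class;
#' blocks left with fewer than two classes at or above `min_haf` after
#' pooling are dropped and listed.
#'
#' @param g imputed [genotype_matrix()]
#' @param blocks a `haplotype_block_set` from [build_blocks()]
#' @param min_haf minimum haplotype-allele frequency (default 0.05)
#' @return the block set with `calls` (lines x blocks character matrix),
#'   `freqs` (post-pooling allele frequencies per block) and `dropped`
#' @export
call_block_alleles <- function(g, blocks, min_haf = 0.05) {
  d <- g$dose
  if (anyNA(d)) stop("missing calls: impute before haplotype calling")
  al <- g$alleles
  spell <- function(marker, x) {
    if (is.null(al)) return(as.character(x / 2))
    row <- al[al$marker == marker, ]
    ifelse(x == 0, row$a0, row$a1)
  }
  kept <- character(0); dropped <- character(0)
  calls <- list(); freqs <- list()
  for (locus in names(blocks$members)) {
    mem <- blocks$members[[locus]]
    letters_by_marker <- vapply(mem, function(mk) spell(mk, d[, mk]),
                                character(nrow(d)))
    allele <- apply(letters_by_marker, 1, paste, collapse = "")
    f <- table(allele) / length(allele)
    rare <- names(f)[f < min_haf]
    pooled <- allele
    pooled[pooled %in% rare] <- "rare"
    pf <- table(pooled) / length(pooled)
    common <- setdiff(names(pf)[pf >= min_haf], "rare")
    n_classes <- length(common) + as.integer("rare" %in% names(pf) &&
                                               pf[["rare"]] >= min_haf)
    if (length(common) < 2 && n_classes < 2) {
      dropped <- c(dropped, locus)
      next
    }
    kept <- c(kept, locus)
    calls[[locus]] <- pooled
    freqs[[locus]] <- as.numeric(pf)
    names(freqs[[locus]]) <- names(pf)
  }
  blocks$blocks <- blocks$blocks[blocks$blocks$locus %in% kept, , drop = FALSE]
  blocks$members <- blocks$members[kept]
  blocks$calls <- if (length(calls)) do.call(cbind, calls) else NULL
  if (!is.null(blocks$calls)) rownames(blocks$calls) <- rownames(d)
  blocks$freqs <- freqs
  blocks$dropped <- dropped
  blocks$min_haf <- min_haf
  blocks
}

#' @export
print.haplotype_block_set <- function(x, ...) {
  cat(sprintf("haplotype_block_set: %d blocks (window %.2f cM), %d singletons%s\n",
              nrow(x$blocks), x$window_cM, nrow(x$singletons),
              if (!is.null(x$dropped) && length(x$dropped))
                sprintf(", %d dropped as rare", length(x$dropped)) else ""))
  invisible(x)
}

#' Polymorphism information content (Botstein)
#'
#' `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`. For a biallelic
#' marker at equal frequencies this peaks at 0.375; it grows with allele
#' number, which is why multi-allelic haplotype loci are more informative
#' than their constituent SNPs.
#'
#' @param freqs allele-frequency vector (non-negative, summing to 1
#'   within 1e-8)
#' @return PIC value in [0, 1)
#' @export
pic <- function(freqs) {
  if (any(freqs < 0)) stop("negative allele frequency")
  if (abs(sum(freqs) - 1) > 1e-8)
    stop("allele frequencies must sum to 1")
  s2 <- sum(freqs^2)
  s4 <- sum(freqs^4)
  1 - s2 - (s2^2 - s4)
}

#' Per-locus PIC for SNPs and haplotype blocks
#'
#' @param g imputed [genotype_matrix()] (for `snp_pic`)
#' @return named numeric vector of PIC values
#' @export
snp_pic <- function(g) {
  d <- g$dose
  p <- colMeans(d) / 2
  vapply(p, function(pp) pic(c(pp, 1 - pp)), numeric(1))
}

#' @rdname snp_pic
#' @param blocks a `haplotype_block_set` with calls
#' @export
block_pic <- function(blocks) {
  if (is.null(blocks$freqs)) stop("call call_block_alleles() first")
  vapply(blocks$freqs, pic, numeric(1))
}

#' Export block descriptions as a data frame
#'
#' One row per block: locus, chromosome, interval, member count, allele
#' count (post-pooling) and PIC — the shape of a published block table.
#'
#' @param blocks a `haplotype_block_set` with calls
#' @return data frame
#' @export
block_summary <- function(blocks) {
  df <- blocks$blocks
  df$n_alleles <- vapply(blocks$freqs[df$locus], length, integer(1))
  df$pic <- unname(block_pic(blocks)[df$locus])
  df[, c("locus", "chrom", "start", "end", "n_snps", "n_alleles", "pic")]
}
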