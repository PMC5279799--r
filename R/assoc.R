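#' Association scan over SNPs and/or haplotype loci
#'
#' Tests each locus against a trait under one of four models:
#' `glm-naive` (no correction), `glm-q` (subpopulation covariates),
#' `mlm-k` (polygenic random effect with covariance K) and `mlm-qk`
#' (both). A SNP enters as a single allele-dose regressor; a haplotype
#' locus enters as `h - 1` indicator columns with the most frequent
#' allele as reference and the pooled `"rare"` class as an ordinary
#' level. Mixed models use EMMA REML; by default variance components are
#' estimated once under the no-locus null and reused per locus (P3D),
#' with exact per-locus REML behind `p3d = FALSE`. The locus term is
#' F-tested on the (whitened, for MLM) least-squares fit; marker R-squared
#' is the percent reduction in residual sum of squares relative to the
#' covariate-only model on the same scale. Adjusted p-values come from
#' [adjust_fdr()]. Allelic effects are computed on the raw trait scale as
#' carrier mean minus panel mean, reporting the largest-magnitude allele
#' (the pooled `"rare"` class never drives the reported effect).
#'
#' @param y named trait vector (names are line ids; NAs dropped)
#' @param snp optional [genotype_matrix()] of SNPs to scan
#' @param blocks optional `haplotype_block_set` with calls to scan
#' @param model one of `"glm-naive"`, `"glm-q"`, `"mlm-k"`, `"mlm-qk"`
#' @param Q membership-probability matrix (lines x groups); one column is
#'   dropped for a full-rank design
#' @param K kinship matrix
#' @param p3d reuse null-model variance components per locus (default)
#' @param map optional [genetic_map()] to annotate SNP positions
#' @param alpha FDR level for significance calls
#' @return data frame of class `assoc_result`, one row per locus:
#'   locus, type, chrom, start, end, nbM, df1, df2, Fstat, p, p_adj,
#'   significant, r2_pct, effect, n. Attributes: `model`, `pi0`, `notes`,
#'   `vc` (MLM variance components), `r2_definition`.
#' @export
assoc_scan <- function(y, snp = NULL, blocks = NULL,
                       model = c("mlm-qk", "glm-naive", "glm-q", "mlm-k"),
                       Q = NULL, K = NULL, p3d = TRUE, map = NULL,
                       alpha = 0.05) {
  model <- match.arg(model)
  if (is.null(snp) && is.null(blocks)) stop("nothing to scan")
  use_q <- model %in% c("glm-q", "mlm-qk")
  use_k <- model %in% c("mlm-k", "mlm-qk")
  if (use_q && is.null(Q)) stop("model ", model, " needs Q")
  if (use_k && is.null(K)) stop("model ", model, " needs K")

  y <- y[!is.na(y)]
  ids <- names(y)
  if (is.null(ids)) stop("y must be a named vector of line means")
  if (!is.null(snp)) ids <- intersect(ids, line_ids(snp))
  if (!is.null(blocks) && !is.null(blocks$calls))
    ids <- intersect(ids, rownames(blocks$calls))
  if (use_q) ids <- intersect(ids, rownames(Q))
  if (use_k) ids <- intersect(ids, rownames(K))
  if (length(ids) < 3) stop("fewer than 3 lines after alignment")
  y <- y[ids]
  n <- length(y)

  X0 <- matrix(1, n, 1)
  if (use_q) {
    Qm <- as.matrix(Q[ids, , drop = FALSE])
    if (ncol(Qm) > 1) X0 <- cbind(X0, Qm[, -1, drop = FALSE])
  }

  # whitening transform (identity for GLM)
  vc <- NULL
  Tw <- diag(n)
  Keig <- NULL
  if (use_k) {
    Km <- as.matrix(K[ids, ids])
    Keig <- .check_psd_eigen(Km)
    vc <- .reml_emma(y, X0, Km)
    Tw <- .whitener(Keig, vc$sigma_g, vc$sigma_e)
  }
  yw <- as.numeric(Tw %*% y)
  X0w <- Tw %*% X0
  qr0 <- qr(X0w)
  p0 <- qr0$rank
  r0 <- qr.resid(qr0, yw)
  rss0 <- sum(r0^2)

  notes <- character(0)
  rows <- list()

  exact_test <- function(Lcols) {
    # exact per-locus REML refit (p3d = FALSE path)
    vc_l <- .reml_emma(y, cbind(X0, Lcols), as.matrix(K[ids, ids]))
    Tl <- .whitener(Keig, vc_l$sigma_g, vc_l$sigma_e)
    yl <- as.numeric(Tl %*% y)
    X0l <- Tl %*% X0
    qr0l <- qr(X0l)
    r0l <- qr.resid(qr0l, yl)
    rss0l <- sum(r0l^2)
    Mr <- qr.resid(qr0l, Tl %*% Lcols)
    qrM <- qr(Mr)
    e1 <- qr.resid(qrM, r0l)
    list(rss0 = rss0l, rss1 = sum(e1^2), df1 = qrM$rank,
         df2 = n - qr0l$rank - qrM$rank)
  }

  add_locus <- function(locus, type, chrom, start, end, nbM,
                        rssf, df1, df2, rss_base, eff) {
    if (df1 < 1 || df2 < 1) return(NULL)
    Fstat <- ((rss_base - rssf) / df1) / (rssf / df2)
    p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
    data.frame(locus = locus, type = type, chrom = chrom,
               start = start, end = end, nbM = nbM, df1 = df1, df2 = df2,
               Fstat = Fstat, p = max(p, .Machine$double.xmin),
               r2_pct = 100 * (rss_base - rssf) / rss_base,
               effect = eff, n = n, stringsAsFactors = FALSE)
  }

  # ---- SNP loci (vectorized under P3D / GLM) ----
  if (!is.null(snp)) {
    D <- snp$dose[ids, , drop = FALSE]
    if (anyNA(D)) stop("missing calls in SNP matrix: impute first")
    if (!is.null(map)) {
      mpos <- map[match(colnames(D), map$marker), , drop = FALSE]
    } else mpos <- NULL
    snp_effect <- function(v) {
      effs <- c(if (any(v == 0)) mean(y[v == 0]) - mean(y) else NA_real_,
                if (any(v == 2)) mean(y[v == 2]) - mean(y) else NA_real_)
      effs <- effs[!is.na(effs)]
      if (!length(effs)) return(NA_real_)
      effs[which.max(abs(effs))]
    }
    if (use_k && !p3d) {
      for (j in seq_len(ncol(D))) {
        v <- D[, j]
        if (stats::sd(v) == 0) {
          notes <- c(notes, paste0(colnames(D)[j], ": monomorphic, skipped"))
          next
        }
        ft <- exact_test(matrix(v))
        rows[[length(rows) + 1L]] <- add_locus(
          colnames(D)[j], "snp",
          if (!is.null(mpos)) mpos$chrom[j] else NA_character_,
          if (!is.null(mpos)) mpos$pos[j] else NA_real_,
          if (!is.null(mpos)) mpos$pos[j] else NA_real_,
          1L, ft$rss1, ft$df1, ft$df2, ft$rss0, snp_effect(v))
      }
    } else {
      Dw <- Tw %*% D
      Dr <- qr.resid(qr0, Dw)
      xx <- colSums(Dr^2)
      xy <- as.numeric(crossprod(Dr, r0))
      for (j in seq_len(ncol(D))) {
        if (xx[j] < 1e-10) {
          notes <- c(notes,
                     paste0(colnames(D)[j],
                            ": monomorphic or collinear with covariates, skipped"))
          next
        }
        rss1 <- rss0 - xy[j]^2 / xx[j]
        rows[[length(rows) + 1L]] <- add_locus(
          colnames(D)[j], "snp",
          if (!is.null(mpos)) mpos$chrom[j] else NA_character_,
          if (!is.null(mpos)) mpos$pos[j] else NA_real_,
          if (!is.null(mpos)) mpos$pos[j] else NA_real_,
          1L, rss1, 1L, n - p0 - 1L, rss0, snp_effect(D[, j]))
      }
    }
  }

  # ---- haplotype loci ----
  if (!is.null(blocks) && !is.null(blocks$calls)) {
    calls <- blocks$calls[ids, , drop = FALSE]
    binfo <- blocks$blocks
    for (locus in colnames(calls)) {
      a <- calls[, locus]
      tab <- sort(table(a), decreasing = TRUE)
      # levels with < 3 carriers are merged into the reference class
      small <- names(tab)[tab < 3]
      if (length(small)) {
        a[a %in% small] <- names(tab)[1]
        notes <- c(notes, paste0(locus, ": level(s) ",
                                 paste(small, collapse = "/"),
                                 " merged into reference (<3 lines)"))
        tab <- sort(table(a), decreasing = TRUE)
      }
      if (length(tab) < 2) {
        notes <- c(notes, paste0(locus, ": single class after merging, skipped"))
        next
      }
      f <- factor(a, levels = names(tab))   # reference = most frequent
      M <- stats::model.matrix(~f)[, -1, drop = FALSE]
      bi <- binfo[binfo$locus == locus, , drop = FALSE]
      hap_eff <- {
        lv <- setdiff(names(tab), "rare")
        effs <- vapply(lv, function(l) mean(y[a == l]) - mean(y), numeric(1))
        if (!length(effs)) NA_real_ else effs[which.max(abs(effs))]
      }
      if (use_k && !p3d) {
        ft <- exact_test(M)
        rows[[length(rows) + 1L]] <- add_locus(
          locus, "hap", bi$chrom, bi$start, bi$end, bi$n_snps,
          ft$rss1, ft$df1, ft$df2, ft$rss0, hap_eff)
      } else {
        Mr <- qr.resid(qr0, Tw %*% M)
        qrM <- qr(Mr)
        e1 <- qr.resid(qrM, r0)
        rows[[length(rows) + 1L]] <- add_locus(
          locus, "hap", bi$chrom, bi$start, bi$end, bi$n_snps,
          sum(e1^2), qrM$rank, n - p0 - qrM$rank, rss0, hap_eff)
      }
    }
  }

  if (!length(rows)) stop("no testable loci after filtering")
  res <- do.call(rbind, rows)
  fdr <- adjust_fdr(res$p, alpha = alpha)
  res$p_adj <- fdr$p_adj
  res$significant <- fdr$significant
  rownames(res) <- NULL
  attr(res, "model") <- model
  attr(res, "p3d") <- p3d
  attr(res, "pi0") <- fdr$pi0
  attr(res, "alpha") <- alpha
  attr(res, "vc") <- vc
  attr(res, "notes") <- notes
  attr(res, "r2_definition") <-
    "percent reduction in residual SS vs covariate-only model, whitened scale for MLM"
  class(res) <- c("assoc_result", "data.frame")
  res
}
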