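#' Pairwise linkage disequilibrium as squared correlation
#'
#' For fully inbred lines the squared Pearson correlation of allele doses
#' equals the classical `D^2 / (pA pa pB pb)`.
#'
#' @param x,y allele-dose vectors over the same lines (no missing calls,
#'   both polymorphic)
#' @return r-squared in [0, 1]
#' @export
pairwise_r2 <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length")
  if (length(x) < 2) stop("need at least 2 lines")
  if (anyNA(x) || anyNA(y)) stop("missing calls: impute before LD")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("monomorphic input: r2 undefined")
  stats::cor(x, y)^2
}

#' Table of pairwise LD over a chromosome, the genome, or unlinked pairs
#'
#' @param g imputed, MAF-filtered [genotype_matrix()]
#' @param map a [genetic_map()]
#' @param scope a chromosome name, `"genome"` (all intra-chromosomal
#'   pairs), or `"interchromosomal"` (pairs on different chromosomes, the
#'   null distribution for the critical r-squared)
#' @param subsample for `"interchromosomal"`: maximum number of pairs,
#'   seeded-subsampled when exceeded (`Inf` enumerates all)
#' @param seed seed for subsampling
#' @return data frame of class `ld_table` with columns marker_i, marker_j,
#'   chrom_i, chrom_j, dist (cM; `NA` for interchromosomal pairs), r2;
#'   attribute `n` holds the line count
#' @export
ld_table <- function(g, map, scope = "genome", subsample = 1e6, seed = 1) {
  d <- g$dose
  if (anyNA(d)) stop("missing calls: impute before LD")
  map <- map[match(colnames(d), map$marker), , drop = FALSE]
  if (anyNA(map$marker)) stop("every marker must be on the map")
  sdv <- .col_sds(d)
  if (any(sdv == 0)) {
    warning(sum(sdv == 0), " monomorphic marker(s) excluded from LD")
    d <- d[, sdv > 0, drop = FALSE]
    map <- map[sdv > 0, , drop = FALSE]
  }

  intra_one <- function(chrom) {
    on <- which(map$chrom == chrom)
    if (length(on) < 2) {
      warning("chromosome ", chrom, " has fewer than 2 markers")
      return(NULL)
    }
    r2 <- stats::cor(d[, on, drop = FALSE])^2
    ut <- which(upper.tri(r2), arr.ind = TRUE)
    data.frame(marker_i = map$marker[on][ut[, 1]],
               marker_j = map$marker[on][ut[, 2]],
               chrom_i = chrom, chrom_j = chrom,
               dist = abs(map$pos[on][ut[, 2]] - map$pos[on][ut[, 1]]),
               r2 = r2[ut], stringsAsFactors = FALSE)
  }

  if (scope == "interchromosomal") {
    set.seed(seed)
    chrom <- map$chrom
    m <- ncol(d)
    total <- (m * (m - 1)) / 2 - sum(table(chrom) * (table(chrom) - 1) / 2)
    if (total < 1) stop("no interchromosomal pairs available")
    if (is.finite(subsample) && total > subsample) {
      keys <- character(0); ii <- integer(0); jj <- integer(0)
      while (length(ii) < subsample) {
        need <- subsample - length(ii)
        a <- sample.int(m, 2 * need, replace = TRUE)
        b <- sample.int(m, 2 * need, replace = TRUE)
        lo <- pmin(a, b); hi <- pmax(a, b)
        ok <- chrom[lo] != chrom[hi]
        lo <- lo[ok]; hi <- hi[ok]
        if (!length(lo)) next
        key <- paste0(lo, "_", hi)
        fresh <- !duplicated(key) & !(key %in% keys)
        ii <- c(ii, lo[fresh]); jj <- c(jj, hi[fresh])
        keys <- c(keys, key[fresh])
        if (length(ii) > subsample) {
          ii <- ii[seq_len(subsample)]; jj <- jj[seq_len(subsample)]
        }
      }
    } else {
      pairs <- which(outer(chrom, chrom, "!="), arr.ind = TRUE)
      pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
      ii <- pairs[, 1]; jj <- pairs[, 2]
    }
    r2 <- vapply(seq_along(ii), function(k)
      stats::cor(d[, ii[k]], d[, jj[k]])^2, numeric(1))
    tab <- data.frame(marker_i = map$marker[ii], marker_j = map$marker[jj],
                      chrom_i = chrom[ii], chrom_j = chrom[jj],
                      dist = NA_real_, r2 = r2, stringsAsFactors = FALSE)
  } else if (scope == "genome") {
    tab <- do.call(rbind, lapply(unique(map$chrom), intra_one))
    if (is.null(tab)) tab <- data.frame(marker_i = character(0),
                                        marker_j = character(0),
                                        chrom_i = character(0),
                                        chrom_j = character(0),
                                        dist = numeric(0), r2 = numeric(0))
  } else {
    if (!scope %in% map$chrom) stop("unknown chromosome: ", scope)
    tab <- intra_one(scope)
    if (is.null(tab)) tab <- data.frame(marker_i = character(0),
                                        marker_j = character(0),
                                        chrom_i = character(0),
                                        chrom_j = character(0),
                                        dist = numeric(0), r2 = numeric(0))
  }
  rownames(tab) <- NULL
  attr(tab, "n") <- nrow(d)
  class(tab) <- c("ld_table", "data.frame")
  tab
}

#' Critical r-squared from the unlinked-pair distribution
#'
#' The background LD threshold is taken from the distribution of
#' r-squared among pairs of markers on different chromosomes. The
#' parametric variant (default) takes the 95th percentile on the
#' square-root scale: `(mean(sqrt(r2)) + z * sd(sqrt(r2)))^2`; the
#' empirical variant takes the plain quantile.
#'
#' @param unlinked an interchromosomal [ld_table()]
#' @param method `"parametric-sqrt"` or `"empirical"`
#' @param q percentile (default 0.95)
#' @return threshold in [0, 1]
#' @export
critical_r2 <- function(unlinked, method = c("parametric-sqrt", "empirical"),
                        q = 0.95) {
  method <- match.arg(method)
  r2 <- unlinked$r2
  if (length(r2) < 2) stop("need at least 2 unlinked pairs")
  if (length(r2) < 30)
    warning("fewer than 30 unlinked pairs: threshold will be unstable")
  if (method == "empirical")
    return(unname(stats::quantile(r2, q)))
  s <- sqrt(r2)
  thr <- (mean(s) + stats::qnorm(q) * stats::sd(s))^2
  min(max(thr, 0), 1)
}

#' Hill-Weir expectation of r-squared at genetic distance d
#'
#' `E[r2] = [(10+C)/((2+C)(11+C))] * [1 + ((3+C)(12+12C+C^2)) /
#' (n(2+C)(11+C))]` with `C = rho * d`. The curve starts near 10/22 for
#' large n and decays to the sampling floor `1/n` as C grows.
#'
#' @param d genetic distance (cM), vectorized
#' @param rho decay-rate parameter (per cM)
#' @param n sample size (number of lines)
#' @return expected r-squared
#' @export
hill_weir_r2 <- function(d, rho, n) {
  C <- rho * d
  ((10 + C) / ((2 + C) * (11 + C))) *
    (1 + ((3 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C)))
}

#' Fit the LD decay curve and locate the decay distance
#'
#' Fits the decay-rate parameter `rho` of the Hill-Weir expectation to
#' intra-chromosomal (distance, r2) pairs by least squares, then finds the
#' smallest distance at which the fitted curve drops to the critical
#' r-squared (bracketed root search, tolerance 1e-4 cM). When the
#' critical value lies at or below the curve's asymptote `1/n`, the curve
#' never crosses and the decay distance is `NA` (flagged).
#'
#' @param intra an intra-chromosomal [ld_table()] (positive distances)
#' @param n number of lines (defaults to the table's `n` attribute)
#' @param critical critical r-squared threshold
#' @return list of class `decay_fit`: `rho`, `n`, `critical_r2`,
#'   `decay_distance` (cM or `NA`), `crosses`, `sse`, `n_pairs`
#' @export
fit_decay <- function(intra, n = attr(intra, "n"), critical) {
  d <- intra$dist; r2 <- intra$r2
  ok <- is.finite(d) & is.finite(r2)
  d <- d[ok]; r2 <- r2[ok]
  if (!length(d)) stop("no intra-chromosomal pairs to fit")
  if (is.null(n)) stop("sample size n is required")
  sse <- function(lr) sum((r2 - hill_weir_r2(d, exp(lr), n))^2)
  opt <- stats::optimize(sse, c(-12, 8), tol = 1e-8)
  if (!is.finite(opt$objective) ||
      opt$minimum < -12 + 1e-6 || opt$minimum > 8 - 1e-6)
    stop("decay fit did not converge: log-rho = ",
         format(opt$minimum), ", sse = ", format(opt$objective))
  rho <- exp(opt$minimum)

  crosses <- critical > 1 / n
  dist <- NA_real_
  if (crosses && hill_weir_r2(1e-6, rho, n) <= critical) {
    dist <- 0   # curve already at/below the threshold at the origin
  } else if (crosses) {
    f <- function(x) hill_weir_r2(x, rho, n) - critical
    hi <- max(d) + 1
    while (f(hi) > 0 && hi < 1e6) hi <- hi * 2
    if (f(hi) <= 0)
      dist <- stats::uniroot(f, c(1e-6, hi), tol = 1e-4)$root
    else crosses <- FALSE
  }
  structure(list(rho = rho, n = n, critical_r2 = critical,
                 decay_distance = dist, crosses = crosses,
                 sse = opt$objective, n_pairs = length(d)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("decay_fit: rho = %.4g /cM, n = %d, critical r2 = %.3f, %s\n",
              x$rho, x$n, x$critical_r2,
              if (x$crosses) sprintf("decay distance = %.2f cM",
                                     x$decay_distance)
              else "curve never crosses the threshold"))
  invisible(x)
}

#' Per-chromosome LD decay distances
#'
#' Convenience wrapper fitting one decay curve per chromosome at a shared
#' critical threshold (the genome-wide fit typically lies within the
#' per-chromosome range).
#'
#' @inheritParams ld_table
#' @param critical critical r-squared
#' @return named numeric vector of decay distances (cM; `NA` where the
#'   curve never crosses)
#' @export
decay_by_chromosome <- function(g, map, critical) {
  chroms <- intersect(unique(map$chrom),
                      map$chrom[match(marker_ids(g), map$marker)])
  out <- stats::setNames(rep(NA_real_, length(chroms)), chroms)
  for (ch in chroms) {
    tab <- suppressWarnings(ld_table(g, map, scope = ch))
    if (!nrow(tab)) next
    fit <- tryCatch(fit_decay(tab, critical = critical),
                    error = function(e) NULL)
    if (!is.null(fit)) out[ch] <- fit$decay_distance
  }
  out
}
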