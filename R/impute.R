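#' Configuration for random-forest genotype imputation
#'
#' @param n_trees trees per marker-specific forest
#' @param n_neighbors flanking markers (nearest by map distance on the
#'   same chromosome) used as predictors
#' @param max_iter refinement sweeps starting from a mode-filled matrix
#' @param seed integer seed (required; forests are randomized)
#' @return an `impute_config`
#' @export
impute_config <- function(n_trees = 100, n_neighbors = 30, max_iter = 2,
                          seed) {
  if (missing(seed)) stop("impute_config requires an explicit seed")
  stopifnot(n_trees >= 1, n_neighbors >= 1, max_iter >= 1)
  structure(list(n_trees = as.integer(n_trees),
                 n_neighbors = as.integer(n_neighbors),
                 max_iter = as.integer(max_iter), seed = as.integer(seed)),
            class = "impute_config")
}

#' Impute missing genotype calls with a random forest
#'
#' For every marker with missing calls, a random-forest classifier is
#' trained on the lines observed at that marker, using the
#' `n_neighbors` nearest mapped markers on the same chromosome as
#' predictors, and the missing lines are predicted. The matrix is first
#' mode-filled, then refined for `max_iter` sweeps in map order
#' (missForest-style), so later markers see already-updated neighbours.
#' Heterozygous input calls are treated as missing and re-imputed to a
#' homozygote (inbred-panel convention). Observed homozygous calls are
#' never altered. Vote ties go to the marker's major allele.
#'
#' @param g a [genotype_matrix()] (post-QC)
#' @param map a [genetic_map()] covering every marker in `g`
#' @param cfg an [impute_config()]
#' @return a [genotype_matrix()] with no missing calls, doses in \{0, 2\}
#' @export
impute_missing <- function(g, map, cfg) {
  if (!inherits(cfg, "impute_config")) stop("need an impute_config")
  d <- g$dose
  if (!all(colnames(d) %in% map$marker))
    stop("every marker must be on the map")
  map <- map[match(colnames(d), map$marker), , drop = FALSE]
  n_het <- sum(d == 1, na.rm = TRUE)
  d[d == 1] <- NA
  target_na <- is.na(d)
  if (!any(target_na)) return(g)
  all_missing <- colSums(!target_na) == 0
  if (any(all_missing))
    stop("marker(s) with all calls missing cannot be imputed: ",
         colnames(d)[which(all_missing)[1]])

  # major allele per marker (ties toward dose 0, deterministically)
  major <- ifelse(colMeans(d == 2, na.rm = TRUE) > 0.5, 2, 0)
  filled <- d
  for (j in seq_len(ncol(d))) filled[target_na[, j], j] <- major[j]

  set.seed(cfg$seed)
  todo <- which(colSums(target_na) > 0)
  for (iter in seq_len(cfg$max_iter)) {
    for (j in todo) {
      same <- which(map$chrom == map$chrom[j] & seq_along(map$chrom) != j)
      if (!length(same)) next           # lone marker: mode fill stands
      nb <- same[order(abs(map$pos[same] - map$pos[j]))]
      nb <- nb[seq_len(min(cfg$n_neighbors, length(nb)))]
      obs <- !target_na[, j]
      y_obs <- d[obs, j]
      if (length(unique(y_obs)) == 1L) {
        filled[!obs, j] <- y_obs[1]
        next
      }
      votes <- .rf_votes(filled[obs, nb, drop = FALSE],
                         as.integer(y_obs == 2),
                         filled[!obs, nb, drop = FALSE], cfg$n_trees)
      pred <- ifelse(votes > 0.5, 2,
                     ifelse(votes < 0.5, 0, major[j]))
      filled[!obs, j] <- pred
    }
  }
  stopifnot(!anyNA(filled), all(filled %in% c(0, 2)),
            all(filled[!target_na] == d[!target_na]))
  out <- .with_dose(g, filled)
  attr(out, "n_het_recoded") <- n_het
  out
}

#' Mode (major-allele) imputation baseline
#'
#' Fills every missing (or heterozygous) call with the marker's major
#' allele. Used as the comparison baseline for the random-forest imputer.
#'
#' @inheritParams impute_missing
#' @return a [genotype_matrix()] with no missing calls
#' @export
impute_mode <- function(g) {
  d <- g$dose
  d[d == 1] <- NA
  major <- ifelse(colMeans(d == 2, na.rm = TRUE) > 0.5, 2, 0)
  for (j in seq_len(ncol(d))) d[is.na(d[, j]), j] <- major[j]
  .with_dose(g, d)
}
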