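#' Configuration for the synthetic-panel generator
#'
#' Describes a structured panel of fully inbred lines: subpopulations
#' diverged under a Balding-Nichols model, along-chromosome linkage
#' disequilibrium induced by a first-order copying process whose
#' correlation decays as `exp(-ld_rho * d)` with map distance `d` (cM),
#' missing calls, and a trait driven by declared QTL plus a marker-based
#' polygenic background and Gaussian noise.
#'
#' Defaults emulate a durum breeding panel: 169 lines in 4 subpopulations
#' over the 14 durum chromosomes, moderate divergence, block-wise LD
#' decaying over a few cM, and up to 10% missing calls.
#'
#' @param n_lines number of inbred lines
#' @param n_subpops number of subpopulations
#' @param fst Balding-Nichols divergence parameter in [0, 1)
#' @param chromosomes named numeric vector: chromosome name -> length (cM)
#' @param markers_per_chrom markers simulated per chromosome
#' @param ld_rho LD decay rate per cM (correlation `exp(-ld_rho * d)`)
#' @param missing_rate fraction of calls set to missing, in [0, 1)
#' @param qtl_spec list of QTL built with [qtl_single()] / [qtl_series()]
#' @param h2_polygenic heritability of the non-QTL genetic background:
#'   polygenic variance is `h2/(1-h2) * noise_sd^2`
#' @param noise_sd residual standard deviation (trait units)
#' @param seed integer seed; same seed gives identical output
#' @return a validated `sim_config`
#' @export
sim_config <- function(n_lines = 169, n_subpops = 4, fst = 0.2,
                       chromosomes = stats::setNames(
                         rep(150, 14),
                         paste0(rep(1:7, each = 2), c("A", "B"))),
                       markers_per_chrom = 100, ld_rho = 0.3,
                       missing_rate = 0.1, qtl_spec = list(),
                       h2_polygenic = 0.4, noise_sd = 1, seed) {
  if (missing(seed)) stop("sim_config requires an explicit seed")
  stopifnot(n_lines >= 2, n_subpops >= 1, markers_per_chrom >= 1)
  if (fst < 0 || fst >= 1) stop("fst must lie in [0, 1)")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (h2_polygenic < 0 || h2_polygenic >= 1)
    stop("h2_polygenic must lie in [0, 1)")
  if (is.null(names(chromosomes)) || any(chromosomes <= 0))
    stop("chromosomes must be a named vector of positive cM lengths")
  if (ld_rho <= 0) stop("ld_rho must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  for (q in qtl_spec) {
    if (!q$chrom %in% names(chromosomes))
      stop("QTL on unknown chromosome: ", q$chrom)
    if (q$start < 0 || q$end > chromosomes[[q$chrom]] || q$start > q$end)
      stop("QTL interval outside chromosome ", q$chrom)
  }
  structure(list(n_lines = n_lines, n_subpops = n_subpops, fst = fst,
                 chromosomes = chromosomes,
                 markers_per_chrom = markers_per_chrom, ld_rho = ld_rho,
                 missing_rate = missing_rate, qtl_spec = qtl_spec,
                 h2_polygenic = h2_polygenic, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Declare QTL for the synthetic panel
#'
#' `qtl_single` places an additive effect on the marker nearest `pos`:
#' carriers of the alternate allele gain `effect` trait units.
#' `qtl_series` realizes an allelic series: the `k` markers closest to the
#' centre of `[start, end]` (all inside the interval) form a local
#' haplotype, and each joint allele pattern (string of 0/1 over the member
#' markers in map order) maps to an effect. Patterns absent from `effects`
#' contribute 0. With effects chosen so that marginal single-SNP contrasts
#' cancel (e.g. an exclusive-or pattern over two members), the series is
#' visible to a haplotype locus but not to any constituent SNP.
#'
#' @param chrom chromosome name
#' @param pos position (cM) for a single-SNP QTL
#' @param effect trait-unit effect of the alternate allele
#' @param start,end interval (cM) containing the series
#' @param k number of member SNPs (2-3 typical)
#' @param effects named numeric: allele pattern (e.g. "010") -> effect
#' @return a QTL descriptor for `sim_config(qtl_spec = list(...))`
#' @export
qtl_single <- function(chrom, pos, effect) {
  list(type = "single", chrom = chrom, start = pos, end = pos,
       effect = effect)
}

#' @rdname qtl_single
#' @export
qtl_series <- function(chrom, start, end, k = 3, effects) {
  if (is.null(names(effects)) || any(nchar(names(effects)) != k))
    stop("`effects` must be named by ", k, "-character 0/1 patterns")
  list(type = "series", chrom = chrom, start = start, end = end, k = k,
       effects = effects)
}

#' Simulate a structured inbred panel with known truth
#'
#' @param config a [sim_config()]
#' @return list of class `sim_panel` with elements `genotypes`
#'   ([genotype_matrix()], doses 0/2 with missing calls), `map`
#'   ([genetic_map()]), `phenotypes` ([phenotype_table()] with trait
#'   `sim_trait`), and `truth` (subpopulation labels, resolved QTL with
#'   member markers and effects, polygenic values)
#' @export
simulate_panel <- function(config) {
  if (!inherits(config, "sim_config")) stop("need a sim_config")
  set.seed(config$seed)
  n <- config$n_lines
  k <- config$n_subpops
  lines <- sprintf("line_%03d", seq_len(n))
  subpop <- rep(seq_len(k), length.out = n)

  maps <- list(); dose_blocks <- list()
  for (chrom in names(config$chromosomes)) {
    len <- config$chromosomes[[chrom]]
    m <- config$markers_per_chrom
    pos <- sort(stats::runif(m, 0, len))
    ids <- sprintf("snp_%s_%04d", chrom, seq_len(m))
    p_anc <- stats::runif(m, 0.05, 0.95)
    # Balding-Nichols subpopulation frequencies
    pf <- matrix(p_anc, nrow = k, ncol = m, byrow = TRUE)
    if (config$fst > 0) {
      a <- (1 - config$fst) / config$fst
      for (s in seq_len(k))
        pf[s, ] <- stats::rbeta(m, p_anc * a, (1 - p_anc) * a)
    }
    # first-order copying process along the chromosome (haplotype level)
    x <- matrix(0L, nrow = n, ncol = m)
    x[, 1] <- stats::rbinom(n, 1, pf[cbind(subpop, 1)])
    if (m > 1) for (j in 2:m) {
      cpy <- stats::rbinom(n, 1, exp(-config$ld_rho * (pos[j] - pos[j - 1])))
      fresh <- stats::rbinom(n, 1, pf[cbind(subpop, j)])
      x[, j] <- ifelse(cpy == 1L, x[, j - 1], fresh)
    }
    maps[[chrom]] <- data.frame(marker = ids, chrom = chrom, pos = pos,
                                stringsAsFactors = FALSE)
    dose_blocks[[chrom]] <- x
  }
  map <- genetic_map(do.call(rbind, maps))
  hap <- do.call(cbind, dose_blocks)
  colnames(hap) <- unlist(lapply(maps, `[[`, "marker"), use.names = FALSE)
  rownames(hap) <- lines
  hap <- hap[, map$marker, drop = FALSE]   # map order

  # trait: QTL + polygenic + noise
  y <- numeric(n)
  qtl_truth <- list()
  for (qi in seq_along(config$qtl_spec)) {
    q <- config$qtl_spec[[qi]]
    on_chrom <- map$chrom == q$chrom
    if (q$type == "single") {
      j <- which(on_chrom)[which.min(abs(map$pos[on_chrom] - q$start))]
      y <- y + q$effect * hap[, map$marker[j]]
      qtl_truth[[qi]] <- list(type = "single", markers = map$marker[j],
                              pos = map$pos[j], chrom = q$chrom,
                              effect = q$effect)
    } else {
      inside <- which(on_chrom & map$pos >= q$start & map$pos <= q$end)
      if (length(inside) < q$k)
        stop("fewer than k markers inside series interval on ", q$chrom)
      # spread members across the interval so the series segregates
      # rather than collapsing into one tightly linked clump
      j <- inside[unique(round(seq(1, length(inside), length.out = q$k)))]
      if (length(j) < q$k)
        j <- inside[seq_len(q$k)]
      j <- sort(j)
      pat <- apply(hap[, map$marker[j], drop = FALSE], 1, paste, collapse = "")
      eff <- config$qtl_spec[[qi]]$effects
      y <- y + ifelse(pat %in% names(eff), eff[pat], 0)
      qtl_truth[[qi]] <- list(type = "series", markers = map$marker[j],
                              pos = map$pos[j], chrom = q$chrom,
                              effects = eff)
    }
  }
  poly <- numeric(n)
  if (config$h2_polygenic > 0 && config$noise_sd > 0) {
    sg2 <- config$h2_polygenic / (1 - config$h2_polygenic) *
      config$noise_sd^2
    sdv <- .col_sds(hap)
    use <- sdv > 0
    Z <- scale(hap[, use, drop = FALSE])
    u <- stats::rnorm(sum(use), 0, sqrt(sg2 / sum(use)))
    poly <- as.numeric(Z %*% u)
  }
  y <- y + poly + stats::rnorm(n, 0, config$noise_sd)

  bases <- c("A", "C", "G", "T")
  pick <- t(vapply(seq_len(ncol(hap)),
                   function(i) sample(bases, 2), character(2)))
  g <- genotype_matrix(2 * hap,
                       data.frame(marker = colnames(hap), a0 = pick[, 1],
                                  a1 = pick[, 2], stringsAsFactors = FALSE))
  if (config$missing_rate > 0)
    g <- inject_missing(g, config$missing_rate)

  pheno <- phenotype_table(data.frame(line = lines, sim_trait = y,
                                      stringsAsFactors = FALSE))
  truth <- list(subpop = stats::setNames(subpop, lines), qtl = qtl_truth,
                polygenic = stats::setNames(poly, lines))
  structure(list(genotypes = g, map = map, phenotypes = pheno,
                 truth = truth, config = config), class = "sim_panel")
}

# colSds without a matrixStats dependency
.col_sds <- function(m) {
  n <- nrow(m)
  cm <- colMeans(m)
  sqrt(pmax(colMeans(m^2) - cm^2, 0) * n / max(n - 1, 1))
}

#' Set genotype calls to missing at random
#'
#' Each call is independently set missing with probability `rate`.
#'
#' @param genotypes a [genotype_matrix()]
#' @param rate missing probability in [0, 1)
#' @param seed optional integer seed; when `NULL` the current RNG stream
#'   is used (as inside [simulate_panel()])
#' @return a [genotype_matrix()] with added missing calls
#' @export
inject_missing <- function(genotypes, rate, seed = NULL) {
  if (!is.numeric(rate) || rate < 0 || rate >= 1)
    stop("rate must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  d <- genotypes$dose
  if (rate > 0) d[stats::runif(length(d)) < rate] <- NA
  .with_dose(genotypes, d)
}

#' Write a simulated panel to standard pipeline inputs
#'
#' Writes genotype TSV (HapMap dialect, plus optional VCF), map CSV,
#' phenotype CSV and the truth record as JSON.
#'
#' @param panel a `sim_panel`
#' @param dir output directory (created if needed)
#' @param vcf also write a VCF copy of the genotypes
#' @return named character vector of paths, invisibly
#' @export
write_panel <- function(panel, dir, vcf = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genotypes = file.path(dir, "genotypes.tsv"),
             map = file.path(dir, "map.csv"),
             phenotypes = file.path(dir, "phenotypes.csv"),
             truth = file.path(dir, "truth.json"))
  write_genotypes(panel$genotypes, paths["genotypes"], "hapmap")
  write_map(panel$map, paths["map"])
  write_phenotypes(panel$phenotypes, paths["phenotypes"])
  jsonlite::write_json(list(subpop = as.list(panel$truth$subpop),
                            qtl = panel$truth$qtl,
                            polygenic = as.list(panel$truth$polygenic)),
                       paths["truth"], auto_unbox = TRUE, digits = NA)
  if (vcf) {
    paths["vcf"] <- file.path(dir, "genotypes.vcf")
    write_genotypes(panel$genotypes, paths["vcf"], "vcf", map = panel$map)
  }
  invisible(paths)
}
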