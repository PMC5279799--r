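#' Configuration for an end-to-end haplotype GWAS run
#'
#' @param genotype_file genotype table (HapMap dialect, dose TSV, or VCF)
#' @param genotype_format `"hapmap"`, `"dose"` or `"vcf"`
#' @param map_file map CSV (marker, chrom, pos in cM)
#' @param phenotype_file phenotype CSV (line, then trait columns)
#' @param out_dir output directory for result tables and the manifest
#' @param max_missing,min_maf marker QC thresholds (defaults 0.25, 0.05)
#' @param window `"fitted"` to use the genome-wide LD decay distance as
#'   the haplotype window, or a fixed width in cM
#' @param models association models to run (see [assoc_scan()])
#' @param fdr_alpha FDR level in (0, 1)
#' @param n_groups subpopulation count for DAPC (or `"auto"`)
#' @param kinship_method `"scaled-ibs"` or `"centered"`
#' @param impute an [impute_config()]
#' @param ld_subsample interchromosomal pairs used for the critical
#'   r-squared
#' @param min_haf minimum haplotype-allele frequency
#' @param seed master seed for every stochastic stage
#' @return a validated `pipeline_config`
#' @export
pipeline_config <- function(genotype_file, genotype_format = "hapmap",
                            map_file, phenotype_file, out_dir,
                            max_missing = 0.25, min_maf = 0.05,
                            window = "fitted", models = "mlm-qk",
                            fdr_alpha = 0.05, n_groups = 4,
                            kinship_method = "scaled-ibs",
                            impute = NULL, ld_subsample = 1e5, seed = 1) {
  for (f in c(genotype_file, map_file, phenotype_file))
    if (!file.exists(f)) stop("input file not found: ", f)
  if (fdr_alpha <= 0 || fdr_alpha >= 1) stop("fdr_alpha must lie in (0, 1)")
  if (!identical(window, "fitted") &&
      (!is.numeric(window) || window <= 0))
    stop("window must be \"fitted\" or a positive width in cM")
  ok_models <- c("glm-naive", "glm-q", "mlm-k", "mlm-qk")
  if (!all(models %in% ok_models))
    stop("unknown model(s): ", paste(setdiff(models, ok_models), collapse = ", "))
  if (is.null(impute)) impute <- impute_config(seed = seed)
  structure(list(genotype_file = genotype_file,
                 genotype_format = genotype_format, map_file = map_file,
                 phenotype_file = phenotype_file, out_dir = out_dir,
                 max_missing = max_missing, min_maf = min_maf,
                 window = window, models = models, fdr_alpha = fdr_alpha,
                 n_groups = n_groups, kinship_method = kinship_method,
                 impute = impute, ld_subsample = ld_subsample,
                 min_haf = 0.05, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full haplotype GWAS pipeline
#'
#' QC -> imputation -> LD decay (critical r-squared from unlinked pairs,
#' Hill-Weir window) -> deduplication -> haplotype blocks -> structure and
#' kinship -> single-SNP and haplotype scans per trait and model ->
#' adaptive FDR -> haplotype/SNP comparison (IVE/IAE). All stage outputs
#' are written as CSV under `out_dir`, together with a JSON manifest
#' holding input checksums, seeds and package version; reruns with the
#' same config reproduce identical tables.
#'
#' @param cfg a [pipeline_config()]
#' @return invisible list with all in-memory stage results
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "pipeline_config")) stop("need a pipeline_config")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "pipeline.log")
  t0 <- Sys.time()
  logline <- function(...) {
    msg <- sprintf("[%6.1fs] %s", as.numeric(Sys.time() - t0, "secs"),
                   paste0(...))
    cat(msg, "\n", file = log_path, append = TRUE)
  }
  stage <- function(name, expr) {
    logline("start ", name)
    out <- tryCatch(expr, error = function(e)
      stop("stage `", name, "` failed: ", conditionMessage(e), call. = FALSE))
    logline("done  ", name)
    out
  }

  g_raw <- stage("read", {
    g <- read_genotypes(cfg$genotype_file, cfg$genotype_format)
    map <- read_map(cfg$map_file)
    pheno <- read_phenotypes(cfg$phenotype_file)
    list(g = g, map = map, pheno = pheno)
  })
  map <- g_raw$map; pheno <- g_raw$pheno

  qc <- stage("qc", qc_filter(g_raw$g, cfg$max_missing, cfg$min_maf))
  utils::write.csv(qc$report$per_marker,
                   file.path(cfg$out_dir, "qc_report.csv"), row.names = FALSE)

  mapped <- stage("map-align", keep_mapped(qc$genotypes, map))
  g_imp <- stage("impute",
                 impute_missing(mapped$genotypes, map, cfg$impute))

  ldres <- stage("ld", {
    unlinked <- ld_table(g_imp, map, scope = "interchromosomal",
                         subsample = cfg$ld_subsample, seed = cfg$seed)
    crit <- critical_r2(unlinked)
    intra <- ld_table(g_imp, map, scope = "genome")
    fit <- fit_decay(intra, critical = crit)
    per_chrom <- decay_by_chromosome(g_imp, map, crit)
    jsonlite::write_json(list(critical_r2 = crit, rho = fit$rho,
                              decay_distance = fit$decay_distance,
                              per_chromosome = as.list(per_chrom)),
                         file.path(cfg$out_dir, "ld_decay.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(intra, file.path(cfg$out_dir, "ld_intra.csv"),
                     row.names = FALSE)
    list(critical = crit, fit = fit, per_chrom = per_chrom)
  })

  window <- if (identical(cfg$window, "fitted")) {
    if (!ldres$fit$crosses || !is.finite(ldres$fit$decay_distance) ||
        ldres$fit$decay_distance <= 0)
      stop("fitted decay distance unavailable; supply a fixed window")
    ldres$fit$decay_distance
  } else cfg$window

  dedup <- stage("dedup", deduplicate(g_imp, map))
  blocks <- stage("blocks", {
    bmap <- map[map$marker %in% marker_ids(dedup$genotypes), , drop = FALSE]
    b <- build_blocks(genetic_map(as.data.frame(bmap)), window)
    b <- call_block_alleles(dedup$genotypes, b, cfg$min_haf)
    utils::write.csv(block_summary(b),
                     file.path(cfg$out_dir, "blocks.csv"), row.names = FALSE)
    b
  })

  struct <- stage("structure",
                  dapc_structure(g_imp, cfg$n_groups, seed = cfg$seed))
  utils::write.csv(data.frame(line = rownames(struct$Q), struct$Q,
                              check.names = FALSE),
                   file.path(cfg$out_dir, "Q.csv"), row.names = FALSE)
  K <- stage("kinship", kinship_matrix(g_imp, cfg$kinship_method))
  utils::write.csv(as.data.frame(unclass(K)),
                   file.path(cfg$out_dir, "K.csv"))

  traits <- names(pheno)[-1]
  scans <- list(); comparisons <- list()
  for (trait in traits) {
    y <- trait_vector(pheno, trait)
    for (model in cfg$models) {
      tag <- paste(trait, model, sep = ".")
      sc <- stage(paste0("scan ", tag), {
        snp_res <- assoc_scan(y, snp = dedup$genotypes, model = model,
                              Q = struct$Q, K = K, map = map,
                              alpha = cfg$fdr_alpha)
        hap_res <- assoc_scan(y, blocks = blocks, model = model,
                              Q = struct$Q, K = K, alpha = cfg$fdr_alpha)
        utils::write.csv(snp_res, file.path(
          cfg$out_dir, paste0("assoc_snp_", tag, ".csv")), row.names = FALSE)
        utils::write.csv(hap_res, file.path(
          cfg$out_dir, paste0("assoc_hap_", tag, ".csv")), row.names = FALSE)
        list(snp = snp_res, hap = hap_res)
      })
      scans[[tag]] <- sc
      cmp <- compare_loci(sc$hap, sc$snp, blocks, map, cfg$fdr_alpha)
      utils::write.csv(cmp, file.path(
        cfg$out_dir, paste0("comparison_", tag, ".csv")), row.names = FALSE)
      comparisons[[tag]] <- cmp
    }
  }

  cors <- stage("correlations", trait_correlations(pheno))
  utils::write.csv(cors$r, file.path(cfg$out_dir, "trait_correlations.csv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("haploscan")),
    seed = cfg$seed,
    inputs = as.list(tools::md5sum(c(cfg$genotype_file, cfg$map_file,
                                     cfg$phenotype_file))),
    critical_r2 = ldres$critical,
    window_cM = window,
    models = cfg$models,
    n_blocks = nrow(blocks$blocks))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  logline("pipeline complete")
  invisible(list(qc = qc, genotypes = g_imp, ld = ldres, window = window,
                 dedup = dedup, blocks = blocks, structure = struct, K = K,
                 scans = scans, comparisons = comparisons,
                 correlations = cors, manifest = manifest))
}
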