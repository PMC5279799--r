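# File formats
#
# HapMap-like TSV ("hapmap"): markers as rows. Columns, in order:
#   marker  alleles  <line id> <line id> ...
# `alleles` is "a0/a1" (e.g. "A/G"). Cells hold the single base for a
# homozygote, the IUPAC ambiguity code for a het, "N" for missing.
#
# Numeric dose TSV ("dose"): same shape; cells hold 0/1/2 or NA.
#
# VCF ("vcf"): sites + GT only; 0/0, 1/1, 0/1, ./.. POS stores the map
# position in centimorgan x 10000 (VCF requires integer coordinates).

.IUPAC_HET <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")

.het_code <- function(a0, a1) {
  key <- paste0(pmin(a0, a1), pmax(a0, a1))
  out <- .IUPAC_HET[key]
  out[is.na(out)] <- "H"   # non-ACGT alleles: generic het marker
  unname(out)
}

.default_alleles <- function(marker_ids) {
  data.frame(marker = marker_ids, a0 = "A", a1 = "G",
             stringsAsFactors = FALSE)
}

#' Write a genotype matrix to disk
#'
#' @param g a [genotype_matrix()]
#' @param path output file
#' @param format one of `"hapmap"`, `"dose"`, `"vcf"`
#' @param map a genetic map (required for `"vcf"`, to place markers)
#' @return `path`, invisibly
#' @export
write_genotypes <- function(g, path, format = c("hapmap", "dose", "vcf"),
                            map = NULL) {
  format <- match.arg(format)
  d <- g$dose
  if (format == "dose") {
    df <- data.frame(marker = colnames(d), t(d), check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  al <- if (is.null(g$alleles)) .default_alleles(colnames(d)) else g$alleles
  if (format == "hapmap") {
    cells <- matrix("N", nrow = ncol(d), ncol = nrow(d))
    for (j in seq_len(ncol(d))) {
      v <- d[, j]
      row <- rep("N", length(v))
      row[!is.na(v) & v == 0] <- al$a0[j]
      row[!is.na(v) & v == 2] <- al$a1[j]
      row[!is.na(v) & v == 1] <- .het_code(al$a0[j], al$a1[j])
      cells[j, ] <- row
    }
    df <- data.frame(marker = colnames(d),
                     alleles = paste0(al$a0, "/", al$a1),
                     cells, check.names = FALSE, stringsAsFactors = FALSE)
    names(df)[-(1:2)] <- rownames(d)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  # vcf
  if (is.null(map)) stop("VCF output needs a genetic map for coordinates")
  map <- map[match(colnames(d), map$marker), , drop = FALSE]
  if (anyNA(map$marker)) stop("every marker must be on the map for VCF output")
  gt <- matrix("./.", nrow = ncol(d), ncol = nrow(d))
  gt[t(d) == 0] <- "0/0"
  gt[t(d) == 1] <- "0/1"
  gt[t(d) == 2] <- "1/1"
  body <- cbind(map$chrom, as.integer(round(map$pos * 1e4)), colnames(d),
                al$a0, al$a1, ".", "PASS", ".", "GT", gt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(d)), collapse = "\t")), con)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a genotype matrix
#'
#' @param path input file
#' @param format `"hapmap"`, `"dose"` or `"vcf"`. VCF parsing is delegated
#'   to the VariantAnnotation package.
#' @return a [genotype_matrix()]
#' @export
read_genotypes <- function(path, format = c("hapmap", "dose", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "dose") {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (names(df)[1] != "marker")
      stop("dose TSV must start with a `marker` column")
    d <- t(as.matrix(df[, -1, drop = FALSE]))
    colnames(d) <- df$marker
    return(genotype_matrix(d))
  }
  if (format == "hapmap") return(.read_hapmap(path))
  .read_vcf(path)
}

.read_hapmap <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty file: ", path)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 3 || hdr[1] != "marker" || hdr[2] != "alleles")
    stop("hapmap TSV header must be: marker, alleles, <line ids>")
  ids <- hdr[-(1:2)]
  nmark <- length(lines) - 1L
  d <- matrix(NA_real_, nrow = length(ids), ncol = nmark)
  markers <- character(nmark)
  a0 <- character(nmark); a1 <- character(nmark)
  for (i in seq_len(nmark)) {
    f <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(hdr))
      stop(sprintf("line %d: expected %d fields, found %d",
                   i + 1L, length(hdr), length(f)))
    markers[i] <- f[1]
    ab <- strsplit(f[2], "/", fixed = TRUE)[[1]]
    if (length(ab) != 2)
      stop(sprintf("line %d: malformed alleles field '%s'", i + 1L, f[2]))
    a0[i] <- ab[1]; a1[i] <- ab[2]
    cells <- f[-(1:2)]
    v <- rep(NA_real_, length(cells))
    v[cells == ab[1]] <- 0
    v[cells == ab[2]] <- 2
    v[cells == .het_code(ab[1], ab[2])] <- 1
    bad <- !(cells %in% c(ab, .het_code(ab[1], ab[2]), "N"))
    if (any(bad))
      stop(sprintf("line %d: unrecognized call '%s' for alleles %s",
                   i + 1L, cells[which(bad)[1]], f[2]))
    d[, i] <- v
  }
  rownames(d) <- ids
  colnames(d) <- markers
  genotype_matrix(d, data.frame(marker = markers, a0 = a0, a1 = a1,
                                stringsAsFactors = FALSE))
}

.read_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("reading VCF requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field")
  d <- matrix(NA_real_, nrow = ncol(gt), ncol = nrow(gt),
              dimnames = list(colnames(gt), rownames(gt)))
  tg <- t(gt)
  d[tg %in% c("0/0", "0|0")] <- 0
  d[tg %in% c("0/1", "1/0", "0|1", "1|0")] <- 1
  d[tg %in% c("1/1", "1|1")] <- 2
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- vapply(VariantAnnotation::alt(vcf),
                function(a) as.character(a)[1], character(1))
  genotype_matrix(d, data.frame(marker = rownames(gt), a0 = ref, a1 = alt,
                                stringsAsFactors = FALSE))
}

#' Read / write a genetic map
#'
#' A genetic map is a data frame with columns `marker`, `chrom` and `pos`
#' (position in centimorgan). Positions must be finite and non-negative;
#' duplicate marker ids are an error.
#'
#' @param path CSV file with columns marker, chrom, pos
#' @return data frame of class `genetic_map`
#' @export
read_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("marker", "chrom", "pos")
  if (!all(need %in% names(df)))
    stop("map CSV needs columns: ", paste(need, collapse = ", "))
  genetic_map(df[need])
}

#' @rdname read_map
#' @param df data frame with columns marker, chrom, pos
#' @export
genetic_map <- function(df) {
  if (anyDuplicated(df$marker))
    stop("duplicate marker id in map: ",
         df$marker[duplicated(df$marker)][1])
  if (!is.numeric(df$pos) || any(!is.finite(df$pos)) || any(df$pos < 0))
    stop("map positions must be finite, non-negative cM values")
  df$chrom <- as.character(df$chrom)
  df <- df[order(df$chrom, df$pos, df$marker), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("genetic_map", "data.frame")
  df
}

#' @rdname read_map
#' @param map a `genetic_map`
#' @export
write_map <- function(map, path) {
  utils::write.csv(as.data.frame(map), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a phenotype table of line means
#'
#' @param path CSV whose first column `line` holds line ids; remaining
#'   columns are numeric trait means.
#' @return data frame of class `phenotype_table`
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "line") stop("phenotype CSV must start with `line`")
  phenotype_table(df)
}

#' @rdname read_phenotypes
#' @param df data frame, first column `line`, then numeric traits
#' @export
phenotype_table <- function(df) {
  if (anyDuplicated(df$line)) stop("duplicate line ids in phenotypes")
  for (j in seq_along(df)[-1]) {
    if (!is.numeric(df[[j]])) stop("trait column not numeric: ", names(df)[j])
    if (any(is.infinite(df[[j]]))) stop("non-finite trait value in ", names(df)[j])
  }
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' @rdname read_phenotypes
#' @param pheno a `phenotype_table`
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.csv(as.data.frame(pheno), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract one trait as a named vector
#' @param pheno a `phenotype_table`
#' @param trait trait column name
#' @return named numeric vector (names are line ids), NAs kept
#' @export
trait_vector <- function(pheno, trait) {
  if (!trait %in% names(pheno)) stop("unknown trait: ", trait)
  stats::setNames(pheno[[trait]], pheno$line)
}

#' Restrict a genotype matrix to mapped markers
#'
#' Markers absent from the map are dropped and reported, mirroring the
#' usual practice of analysing only markers placed on a consensus map.
#'
#' @param g a [genotype_matrix()]
#' @param map a [genetic_map()]
#' @return list with `genotypes` (mapped subset) and `unmapped`
#'   (character vector of dropped marker ids)
#' @export
keep_mapped <- function(g, map) {
  unmapped <- setdiff(marker_ids(g), map$marker)
  kept <- setdiff(marker_ids(g), unmapped)
  if (length(unmapped))
    message(length(unmapped), " marker(s) not on the map were dropped")
  list(genotypes = subset_genotypes(g, markers = kept), unmapped = unmapped)
}
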