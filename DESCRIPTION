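Package: haploscan
Title: Haplotype-Block Association Mapping for Inbred Crop Panels
Version: 0.1.0
Authors@R:
    person("Durum", "Panel Tools", email = "haploscan@example.org",
           role = c("aut", "cre"))
Description: Tools for haplotype-based genome-wide association analysis in
    inbred crop panels. Implements linkage-disequilibrium decay estimation
    with the Hill-Weir expectation, construction of LD-window haplotype
    blocks from mapped SNPs, random-forest genotype imputation, population
    structure inference by discriminant analysis of principal components,
    kinship computation, single-SNP and multi-allelic haplotype association
    scans under general linear and mixed linear models (Q + K), adaptive
    false-discovery-rate control, and statistics quantifying the gain of
    haplotype loci over single SNPs in variance explained and allelic
    effect. Includes a synthetic-panel generator with known QTL
    architecture for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
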