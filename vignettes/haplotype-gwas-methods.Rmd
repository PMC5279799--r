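---
title: "Methods: haplotype-block association mapping in inbred panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype-block association mapping in inbred panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette records the models behind `haploscan`, the choices made
where the design was genuinely open, what the synthetic-panel generator
does and does not emulate, and the package's known limitations. It
states no empirical result that the test suite or the acceptance script
does not itself compute.

## 1. The problem and the pipeline

Breeding panels of inbred lines are genotyped at thousands of mapped
biallelic SNPs and phenotyped as line means. Single-SNP association
scans lose power when a locus carries an allelic series: several linked
functional variants whose joint haplotype, not any single marker,
determines the effect. The pipeline therefore (i) estimates the panel's
LD decay, (ii) groups mapped SNPs into windows of that width and treats
each window as one multi-allelic locus, and (iii) scans both SNP and
haplotype loci under identical model corrections so their results are
comparable locus for locus.

Stage order: QC → imputation → LD decay → deduplication → blocks →
structure/kinship → association → FDR → haplotype/SNP comparison.

## 2. Genotype QC and imputation

Doses are coded 0/2 for homozygotes (inbred lines), 1 for residual
heterozygous calls, `NA` for missing. Markers with more than 25%
missing calls or minor-allele frequency below 0.05 are removed; MAF is
computed on non-missing calls *before* imputation (the alternative —
after imputation — would let imputed calls rescue borderline markers;
computing before is standard and recorded in the QC report).
Heterozygous calls are tolerated on input but treated as missing by all
LD and haplotype computations: in an effectively homozygous panel they
are overwhelmingly genotyping artefacts.

Missing calls are imputed by a random-forest classifier per marker,
trained on the lines observed at that marker with the `n_neighbors`
(default 30) nearest mapped markers on the same chromosome as
predictors, starting from a mode-filled matrix and sweeping `max_iter`
(default 2) times in map order. The forest is implemented in-package
(bootstrap resampling, random feature subset at every split, Gini CART
on binary dose predictors) because no tree-ensemble package is part of
the supported dependency set; with binary predictors every split
threshold is 1, so this is a faithful, compact random forest.
Defaults (`n_trees = 100`, 30 neighbours, 2 sweeps) sit past the
accuracy plateau on block-LD data; tests use smaller forests purely for
speed. Predicted doses are the majority vote; exact ties go to the
marker's major allele, so output is deterministic given the seed.

## 3. LD decay and the haplotype window

LD between two markers is the squared Pearson correlation of doses,
which for inbred lines equals the haplotype-frequency form
`D²/(p_A p_a p_B p_b)`. The *critical r²* separating linkage-driven LD
from background is the parametric 95th percentile of r² over pairs of
markers on different chromosomes, computed on the square-root scale as
`(mean(√r²) + 1.6449 · sd(√r²))²` — the transform follows the
methodology the threshold convention derives from; a plain empirical
quantile is available (`method = "empirical"`). Interchromosomal pairs
are seeded-subsampled (default 10⁶) because full enumeration at ~8,500
markers is ~36 M pairs.

Decay is modelled by the Hill–Weir drift expectation with `C = ρd`
(see `hill_weir_r2()`); ρ is fitted by least squares via golden-section
search on log ρ over [e⁻¹², e⁸], with an error (carrying the optimizer
state) if the optimum pins to a bound. The expectation tends to `10/22`
at the origin for large n and to the sampling floor `1/n` as C → ∞, so
a critical value at or below `1/n` can never be crossed; this is
flagged rather than silently returning a distance. Otherwise the decay
distance solves `E[r²](d) = critical` by bracketed root search
(tolerance 10⁻⁴ cM). Both the genome-wide decay distance and
per-chromosome distances are reported, since the genome-wide "average
LD distance" is ambiguous between the two readings; the genome-wide fit
is the default haplotype window.

A practical caveat established while designing the tests: in a clean
synthetic panel with unlinked chromosomes the interchromosomal r²
distribution sits at the `1/n` sampling floor, so the critical r² is
~0.02 at n = 169 and the fitted window becomes tens of cM. Real panels
show much higher background LD (structure, relatedness), which is what
makes published critical values like 0.2 and windows of ~5 cM
realistic. Pipelines on synthetic data should therefore either use a
fixed window or simulate background relatedness.

## 4. Blocks, haplotype alleles, PIC

Within a chromosome, markers with identical dose vectors (directly or
after a global allele flip — the same partition of lines) collapse to
the representative with the smallest cM. Each chromosome is then cut
into half-open windows `[s, s+w)` anchored at its first marker — the
anchoring is a convention chosen because it is deterministic and
order-free; windows with ≥ 2 markers become loci named
`hap_<chrom>_<index>`, the index counting emitted blocks only (published
indices cannot be matched without the original map, so naming is
convention-compatible, not index-identical). Singleton windows are kept
as plain SNPs.

A line's block allele is the ordered concatenation of member-SNP
alleles. Alleles below 5% frequency pool into one `"rare"` class rather
than being set missing — pooling preserves sample size; the pooled class
is a legitimate factor level in association tests but never drives the
reported allelic effect. A block whose post-pooling spectrum has fewer
than two classes at ≥ 5% is dropped and listed.

Informativeness uses the Botstein PIC,
`1 − Σp²ᵢ − Σ_{i<j} 2p²ᵢp²ⱼ`, which peaks at 0.375 for a biallelic
marker and grows with allele count — the mechanism by which haplotype
loci carry more information than their constituent SNPs (the property
suite checks multi-allelic PIC dominates every biallelic collapse).

## 5. Structure and kinship

Q comes from discriminant analysis of principal components: the dose
matrix is centred, at most `floor(N/3)` PCs are retained (56 for a
169-line panel), lines are clustered by k-means on the retained scores,
and a linear discriminant analysis on those scores yields membership
probabilities. For regression use one Q column is dropped (full rank).

When `n_groups = "auto"`, k is selected by the ICL (BIC plus assignment
entropy) of an equal-variance diagonal Gaussian mixture fitted by EM on
the three leading standardized PCs. The more obvious k-means/BIC scan
was rejected after measurement: in a high-dimensional PC space,
splitting even unstructured noise reduces within-cluster sums of
squares by far more than a `log(n)` penalty, so that criterion
essentially never returns k = 1. The ICL criterion is conservative by
construction — it will under-call weak structure at small n — which is
the appropriate failure mode for a covariate meant to absorb
confounding; fixed k is recommended whenever the panel's structure is
known.

Kinship defaults to scaled identity-by-state — mean allele sharing
rescaled as `(s − min)/(1 − min)` — emulating the common GWAS-toolkit
default for inbred panels; the centred/VanRaden cross-product
(`ZZ'/(2Σpq)`) is the alternative. The method is recorded in the matrix
attributes because downstream variance components are only
interpretable jointly with it.

## 6. Association models

For a trait vector over n lines, a SNP contributes a 1-df dose
regressor; a haplotype locus contributes h−1 indicators against the
most frequent allele as reference, with levels carried by fewer than 3
lines merged into the reference (logged) so no test is driven by 1-2
lines. Models: `glm-naive`, `glm-q`, `mlm-k`, `mlm-qk`.

The mixed model `y = Xβ + locus + u + e`, `Var(u) = σ²_g K`,
`Var(e) = σ²_e I`, is estimated by EMMA-style REML: the restricted
likelihood is profiled over δ = σ²_e/σ²_g using the spectral
decomposition of `S K S` (S projecting off the fixed effects), scanned
on an 81-point log grid and refined by golden-section search. By
default the components are estimated once under the no-locus null and
reused for every locus (P3D); with `p3d = FALSE` the REML is re-solved
per locus. At desk-scale n the two differ negligibly while P3D is
orders of magnitude faster. Given components, V is whitened through
the eigendecomposition of K and every locus is an OLS F-test on the
transformed data — the test suite proves this path equal to a
closed-form GLS oracle at the same components to 10⁻⁸, and equal to
the naive GLM when K = I.

Marker R² is defined as the percent reduction in residual sum of
squares relative to the covariate-only model, on the whitened scale for
mixed models. This is a package decision (toolkit formulas for "marker
R²" under MLM are not standardized); it is recorded in the result
attributes, and the IVE comparison is internally consistent because
both SNP and haplotype scans use the same definition.

Multiplicity is controlled by the Storey–Taylor–Siegmund adaptive
step-up: `π̂₀ = (#{p > λ} + 1)/(m(1 − λ))` capped at 1, with
`λ = α/(1+α)`, then Benjamini–Hochberg step-up with `m·π̂₀`. Loci with
adjusted p below α = 0.05 are declared significant. `qq_points()`
exports expected-vs-observed −log₁₀ p for model diagnostics; under the
uniform null the bulk of points hugs the diagonal while the extreme
order statistic alone fluctuates by ~0.4, so diagnostics (and the
tests) should read the bulk, not the top point.

## 7. Effects, IVE/IAE, derived traits

The allelic effect of an allele is the mean trait value of its carrier
lines minus the whole-panel mean; the locus-level effect is the
largest-magnitude allele effect, excluding the pooled `"rare"` class.
Each significant haplotype locus is matched to the significant SNP
whose map position falls inside the block interval (smallest p wins if
several; unmatched loci keep empty SNP fields), and

    IVE = 100 · (R²_hap − R²_snp) / R²_snp
    IAE = 100 · (|eff_hap| − |eff_snp|) / |eff_snp|

are averaged over matched pairs. Against the published reference table
of matched durum colour-trait pairs, the reconstruction reproduces all
eleven IVE cells and nine of eleven IAE cells exactly at one decimal;
the two discrepant pigment-loss IAE cells are inconsistent with their
own printed effects (most plausibly an artefact of effect rounding in
the source table) and are deliberately not "corrected".

Colour loss is the residual of pasta b* regressed on semolina b*
(OLS with intercept; residuals sum to zero; positive = less pigment
loss than average). Trait correlations are pairwise Pearson r with
two-sided p-values; candidate-gene LD reuses `pairwise_r2` between
association signals and gene-linked markers.

## 8. The synthetic panel: what it does and does not emulate

`simulate_panel()` generates fully inbred lines (doses 0/2 — hets are
not simulated) in `n_subpops` subpopulations whose allele frequencies
diverge from a common ancestor by a Balding–Nichols Beta model at the
stated F_ST. Along each chromosome, a first-order copying process
induces LD: marker m copies marker m−1 with probability
`exp(−ρ·Δd)`, else draws fresh from the subpopulation frequency, so
adjacent-marker correlation decays at the controlled rate ρ — chosen
over coalescent simulation for speed and because the decay rate is the
directly controlled quantity. Defaults state the emulated world: 169
lines, 4 subpopulations, F_ST 0.2 (a moderate crop-panel divergence;
the source panel's F_ST is not published), 14 chromosomes of 150 cM,
ρ = 0.3/cM, 10% missing calls, polygenic heritability 0.3-0.4 of the
non-QTL variance.

QTL are declared as single-SNP effects or allelic series: k markers
spread evenly across a stated interval (spreading, rather than taking
the k markers nearest the centre, is deliberate — centre-packed members
are so tightly linked that the joint haplotype barely segregates and
the series degenerates), with effects keyed to the joint 0/1 pattern.
Patterns that reward disagreement between adjacent members (exclusive-
or) produce loci visible to a haplotype scan but nearly invisible to
any constituent SNP — the mechanism of interest. The phenotype adds a
polygenic term built from standardized marker dosages scaled so its
variance is `h²/(1−h²)·σ²_noise`, plus Gaussian noise; the polygenic
term is what makes Q+K corrections genuinely necessary in simulations.

Not emulated: pedigree structure and within-family relatedness beyond
the marker-driven polygenic term (kinship intensity is a free parameter
of the world, as nothing is published about it), selection and drift
dynamics, genotyping error other than missingness, multi-environment
trial structure (line means are the unit), and realistic site-frequency
spectra (ancestral frequencies are uniform on [0.05, 0.95]). A green
test on this generator therefore establishes that the *methods* behave
as claimed under a controlled stochastic world — not that any particular
published dataset-level count (block totals, significant-locus counts)
would be reproduced; those depend on the undeposited panel.

## 9. Numerical choices and degenerate inputs

* REML δ scanned on log grid [−10, 10]; K eigenvalues clamped at 0 and
  a non-PSD K (beyond numerical tolerance) is an error, not a shift.
* F-test p-values are floored at the smallest positive double so
  downstream FDR (which requires p > 0) never sees an exact 0.
* Collinear or monomorphic loci are skipped with a logged note rather
  than producing NaN rows.
* Dedup ties (equal cM) break lexicographically by marker id; imputation
  vote ties break to the major allele; window anchoring is the first
  marker per chromosome — all chosen to make every output a pure
  function of (inputs, config, seed), which the pipeline test verifies
  byte-for-byte.
* `fit_decay` distinguishes three outcomes: a crossing (distance), a
  curve entirely below the threshold (distance 0), and a threshold at or
  below `1/n` (undefined, flagged).

## 10. Known limitations

* The imputation forest is O(markers × trees) in R; at the scale of
  hundreds of thousands of markers a compiled learner would be needed.
* Exact per-locus REML (`p3d = FALSE`) is provided for verification, not
  speed.
* Haplotype phase is trivial only because lines are inbred; the package
  must not be applied to outbred heterozygous material.
* The auto-k selector is conservative at small n (see §5).
* Published block indices (`hap_5B_25` and the like) are not
  reproducible without the original consensus map; only the naming
  convention is shared.
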