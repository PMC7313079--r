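---
title: "Haploblock enrichment analysis of landrace panels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haploblock enrichment analysis of landrace panels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haploscan)
```

## Scope

`haploscan` implements an analysis chain for SNP panels of predominantly
self-fertilizing crops (landrace collections in particular): marker
filtering, linkage-disequilibrium (LD) characterization, haploblock
partitioning, mixed-model genome-wide association (GWAS) of phenotypes and
of bioclimatic variables treated as "extended phenotypes", a GSEA-style
haploblock enrichment test over the GWAS rankings, and bi-clustering of
traits by the haploblocks they share. A synthetic-data generator with
planted ground truth makes every stage testable end to end.

This vignette documents the statistical models, the tunable parameters and
their defaults, the numerical choices, and what the synthetic experiments
do and do not demonstrate about real data.

## The genotype model and marker filters

Genotypes are biallelic SNP dosages (0/1/2 alternate-allele copies, `NA`
for missing) with 1-based VCF coordinates; block intervals are closed
`[start_bp, end_bp]`. Multi-allelic and indel records are skipped on
import rather than split, because splitting makes dosages ambiguous and the
intended panels are biallelic SNP sets. Heterozygous calls are kept as
dosage 1 even in selfing species: residual heterozygosity is real in
landraces.

`filter_variants()` retains markers with call rate at least
`min_call_rate` (default 0.90) and minor allele frequency at least
`min_maf` (default 0.03), with MAF computed on the alleles of non-missing
genotypes only (the usual VCFtools semantics). Both thresholds are
inclusive ("at least"), and the filter is idempotent.

## LD: r², the unlinked critical value, and the decay range

Pairwise LD is the squared Pearson correlation of dosage columns over
pairwise-complete samples (composite LD on genotypes). In a highly selfing
panel most individuals are homozygous, so dosage r² closely tracks
haplotype r²; this avoids phasing entirely. Pairs with fewer than 20
complete samples or a monomorphic column are dropped.

The *critical value* separating background association from physical
linkage is taken from r² between markers on *different* chromosomes: by
default the parametric 95th percentile `mean + 1.645 * sd` of the unlinked
distribution (an empirical-quantile mode is available). Unlinked pairs are
subsampled (default 100,000) with a dedicated child seed.

The *decay range* is where a degree-2 LOESS of intra-chromosomal r² on
physical distance first drops to the critical value, located by linear
interpolation between evaluation points; a flag reports curves that never
cross. On dense panels the number of intra-chromosomal pairs grows
quadratically, so above `max_points` (default 20,000) pairs are aggregated
into 2,000 equal-count distance bins (mean distance, mean r², bin count as
LOESS weight) before fitting. Binning changes the fitted curve negligibly
— the LOESS sees the same conditional means — while keeping the cost
bounded; the crossing-recovery test against an analytic exponential decay
passes identically with and without aggregation.

## Haploblocks from |D'| confidence intervals

Blocks are defined by the confidence-interval method: for each marker pair
within `max_block_span_bp` (default 500 kb, the conventional search
window), two-locus haplotype frequencies are estimated by EM over unphased
genotypes (only the double heterozygote is phase-ambiguous; convergence at
relative log-likelihood change below 1e-10 or 1,000 iterations, initialized
at linkage equilibrium). The likelihood of the 3x3 genotype table is then
evaluated on a |D'| grid (step 0.001) with allele frequencies fixed at
their estimates and the sign fixed at the point estimate's; the normalized
curve's 5th and 95th cumulative points give a 90%-mass interval. Grid
discretization can leave a boundary MLE (|D'| = 1) just above the upper
cumulative point, so the interval is widened to contain the point estimate.

Pairs are classified *strong LD* when `ci_low >= 0.70` and
`ci_high >= 0.98`, *recombination* when `ci_high < 0.90`, otherwise
*uninformative*. A candidate block is a contiguous marker run whose
outermost pair is strong LD and in which at least `informative_fraction`
(default 0.95) of informative pairs are strong LD; candidates are accepted
greedily by descending marker count (ties: longer span, then leftmost),
discarding overlaps. The separate Haploview special cases for 2-4 marker
blocks are deliberately collapsed into this single fraction rule: the
simplification is parameterized and makes the definition uniform across
block sizes. A per-pair MAF floor (Haploview's own default would be 0.05)
is exposed but off by default, since the panel-level 3% MAF filter already
applies; rare-allele pairs that reach |D'| = 1 spuriously can create small
blocks, which the enrichment stage's size filter removes anyway.

The likelihood assumes random union of gametes. Under intense selfing,
genotype frequencies deviate from that assumption; in practice the
homozygote-dominated tables still localize |D'| well (the recovery tests
below run at ~95% homozygosity), but the intervals should be read as
approximate in strongly inbred material.

## Mixed-model GWAS

For each trait `y` (ordinal traits as integer scores) the single-locus
linear mixed model is

    y = X b + g + e,   g ~ N(0, s2_g K),   e ~ N(0, s2_e I)

with `K = Z Z' / m` the realized relationship matrix of standardized
dosages. The spectral decomposition `K = U S U'` turns the covariance
diagonal in rotated coordinates; the variance ratio `delta = s2_e / s2_g`
is estimated once per trait by maximizing the REML profile likelihood over
`log delta` in `[-10, 10]` (41-point grid, then local refinement). REML
rather than ML keeps variance components unbiased at panel-scale `n`; the
difference is immaterial here but documented. Each SNP is then tested by a
1-df Wald chi-square in the rotated GLS fit with the SNP in the fixed
effects. One global `K` serves all SNPs — the candidate is *not* removed
from `K` (no leave-one-chromosome-out). This matches common practice and
costs a little power when the causal signal is a large share of the panel
(proximal contamination); the package's own recovery experiments therefore
plant signals that are a small fraction of the panel, as in real data.

Fixed covariates default to the top 8 genotype principal components
(dosages mean-imputed, centered, scaled); a geographic variant appends the
first 2 principal coordinates (classical metric scaling of haversine
distances between collection sites, default `k = 2`). Missing dosages are
mean-imputed per variant; missing trait values drop the sample.

Per trait, 1-df statistics are deflated by the genomic-control factor
`lambda = median(stat) / qchisq(0.5, 1)` when `lambda > 1` (unchanged
otherwise), and Benjamini-Hochberg q-values are computed from the adjusted
p-values — genomic control first, FDR second. Significance is `q < 0.05`.

## Haploblock enrichment

The enrichment test asks whether a haploblock's SNPs concentrate near the
top of the trait's ranking of all panel SNPs by increasing (adjusted)
p-value, with positional tie-breaks. The rank statistic is `-log10(p)`
capped at 300; the running sum gains `stat^alpha / sum(hit stats^alpha)`
at each member SNP and loses `1 / (N - block size)` elsewhere, and the
enrichment score (ES) is the signed maximal deviation (the positive
deviation is preferred on an exact tie). `alpha = 1` (default) weights
hits by their statistic; `alpha = 0` recovers the unweighted
Kolmogorov-Smirnov form, making the score invariant to any
ranking-preserving transform of p. Blocks are pre-filtered to more than 6
member SNPs, a size below which the running-sum statistic is dominated by
single markers.

The permutation null draws random SNP sets of matched size without
replacement from the panel — equivalently, permuting set labels over the
fixed ranking — with one seeded permutation stream per trait, reused across
blocks by size stratification. P-values are positive-tail only,
`p = (1 + #[null ES >= observed ES]) / (n_perm + 1)` (default
`n_perm = 100,000`), because the significance rule uses only positive ES;
BH correction is applied within trait across blocks (a global-FDR option
exists), and a block is *enriched* when `ES > 0` and `q < 0.05`.
Enrichment runs on the 8-PC GWAS results by default; the PCoA-augmented
variant is selectable. Note the null treats SNPs as exchangeable: LD makes
member p-values co-move, which the type-I experiment below shows is
tolerable at the FDR level on this design, but the test shares this
caveat with all set-enrichment methods applied to correlated items.

## Trait similarity and bi-clustering

Each trait's signature is its set of enriched blocks. Similarity between
two traits is the Sørensen-Dice coefficient `2 |a ∩ b| / (|a| + |b|)` —
the doubly-counted shared blocks normalized by the two set sizes, the only
reading of "common blocks over all blocks of the two traits" that is
symmetric and bounded by 1. Two empty sets score 0 by convention and such
traits are flagged. Because rows and columns of the similarity matrix
index the same traits, "bi-clustering" is one agglomerative hierarchical
clustering (average linkage on `1 - score`) applied to both axes, with
label-alphabetical tie-breaking for determinism. The flat-group cut height
is a free parameter (default 0.5 on the dissimilarity scale); there is no
canonical height, and readers of the heatmap should treat flat groups as a
visual aid rather than an inference.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
not the biology that produces it:

* **Founder-haplotype blocks.** Within each planted block every gamete
  carries one of a small founder pool (drawn with group-specific
  frequencies; Dirichlet-perturbed with concentration `(1 - Fst) / Fst`,
  default `Fst = 0.15`), so block markers are in strong mutual LD;
  between blocks and at background markers gametes recombine freely, with
  background allele frequencies following Balding-Nichols group
  differentiation.
* **Selfing.** Each accession's second gamete is a copy of the first with
  probability `selfing_inbreeding` (default 0.95), reproducing the
  homozygosity-dominated dosage distribution of a selfing crop without a
  coalescent model.
* **Missingness** is uniform at random (default 3%) — no mechanism is
  modeled because none is specified for the motivating data.
* **Traits** are causal-block effects plus a polygenic background plus
  Gaussian noise, each component rescaled to its configured variance
  share (`heritability * (1 - polygenic_share)`,
  `heritability * polygenic_share`, `1 - heritability`). Ordinal traits
  threshold the latent value at equal-probability quantiles. Planted
  effect sizes are free parameters of the experiments, chosen for the
  power regime under study; they are not estimates of any real panel's
  effects.
* **Geography and bioclim.** Groups get centroid coordinates (six
  historic cultivation centers by default) with Gaussian jitter;
  bioclimatic variables form correlation blocks sharing a group-level mean
  and a per-sample latent factor (target within-block correlation 0.9),
  independent across blocks. Climate rasters are not emulated — only the
  correlation structure the downstream analysis consumes.
* **Determinism.** One global seed fans out to named child seeds per
  stage (`simulate`, `traits`, `geo`, `unlinked`, `perm`), so any stage
  can be re-run reproducibly in isolation.

The default panel is 400 accessions, 8 chromosomes, 2,579 SNPs with
strongly uneven density (91 on the shortest chromosome, 792 on the
densest), 6 geographic groups and 40 planted 10-SNP blocks.

What passing tests on this generator show: the block partitioner recovers
founder-LD structure; the mixed model is calibrated under the null and
powered against planted signals; the enrichment test controls its FDR
under exchangeable nulls and detects concentrated signals; the similarity
clustering separates planted pleiotropy groups. What they do not show:
robustness to realistic recombination gradients, ascertainment bias of
reduced-representation genotyping, non-random missingness, phenotype
measurement structure (year, field position), or climate-raster artifacts.

## Numerical choices and degenerate inputs

* EM tolerance 1e-10 (relative log-likelihood), 1,000-iteration cap;
  |D'| grid step 0.001; all-zero haplotype cells floored at 1e-12 inside
  logs.
* LOESS span default 0.3; decay crossing by linear interpolation on a
  400-point evaluation grid; curves that never cross return a flag, not a
  number.
* Pairs with under 20 complete samples are dropped (LD) or classified
  uninformative (partitioning); monomorphic inputs error in user-facing
  calls.
* The Mann-Whitney test enumerates all group assignments exactly (with
  average ranks for ties, two-sided via distance of U from its mean) when
  the combined size is at most 20, and uses the tie-corrected normal
  approximation above that.
* BH q-values delegate to `p.adjust(method = "BH")`, which implements the
  step-up formula exactly; the permutation p floor is `1 / (n_perm + 1)`.
* `lambda <= 1` leaves statistics unadjusted: genomic control corrects
  inflation only.

## Problem sizes used by the test suite

The packaged experiments run at desk scale, chosen to keep the full suite
in the minutes range while leaving each conclusion statistically stable:
type-I error uses 20 null traits on the 2,000-SNP/40-block panel at
`n_perm = 10,000` (scaled down from the 100,000-permutation analysis
default); power uses 50 replicates of a planted block explaining 20% of
trait variance at `n_perm = 4,000` (resolution well below the BH
threshold at 40 blocks); bi-clustering recovery uses 25 replicates of two
3-trait pleiotropy groups; block recovery uses 20 seeds of a 6-block
panel at `n = 400`; the exhaustive enrichment oracle uses panels of at
most 12 SNPs where all same-size sets can be enumerated.

## Known limitations

* No leave-one-chromosome-out kinship: power loss when planted signals
  are a large fraction of the panel (documented above; visible if the
  panel is shrunk below ~10x the causal set).
* The |D'| CI likelihood assumes random mating; intervals are
  approximate under intense selfing.
* The enrichment null ignores LD between ranked SNPs; FDR control was
  verified empirically on this design only.
* Ordinal phenotypes are analyzed as integer-coded linear traits, as is
  common when one model must serve a large mixed descriptor set.
* "Bi-clustering" is symmetric-matrix seriation by one dendrogram, not a
  checkerboard bi-cluster model.
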