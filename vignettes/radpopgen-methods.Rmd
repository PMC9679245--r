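---
title: "Methods: population-genomic analysis of RAD-capture SNP data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-genomic analysis of RAD-capture SNP data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radpopgen)
```

`radpopgen` implements a complete analysis path for reduced-representation
(RADseq / Rapture) SNP genotypes from wild populations — the kind of data used
to delineate fishery stocks such as Lake Michigan lake whitefish (*Coregonus
clupeaformis*): quality control, population structure and diversity,
isolation by distance over in-water paths, PCA-based genome scans with
sliding-window detection of genomic islands of divergence, linkage
disequilibrium (LD) permutation tests, and a local-PCA screen for putative
chromosomal inversions. This vignette documents the models, the defaults and
why they were chosen, the numerical decisions, and what the synthetic-data
generator does and does not emulate.

## Data model

Genotypes live in a `geno_set`: an individuals × SNPs matrix of alternate
allele dosages (0/1/2, `NA` missing), aligned SNP and sample tables, and
optional per-cell allele depths. The alternate-allele orientation is used
consistently: every allele frequency `p` in the package is the alternate
allele frequency. VCF import goes through `vcfR`; only biallelic SNPs are
kept, and records failing that contract are dropped and counted rather than
silently coerced.

## Quality control

`filter_cascade()` applies, in a fixed order: minor allele count (MAC ≥ 3 by
default), SNP call rate (≥ 0.70), then individual missingness (≤ 0.50)
*recomputed on the retained SNPs*. The order matters — an individual's
missingness is judged against markers that survived the SNP-level filters —
and the per-step report makes it auditable. The thresholds are the
conventional Rapture-pipeline values; all are configuration, not constants,
because panel-development and production stages of such pipelines commonly use
different call-rate cutoffs (e.g. 0.30 at discovery vs 0.70 at genotyping).

The paralog screen (`hdplot_filter()`) computes, per SNP, the heterozygote
fraction H and the pooled read-ratio deviation
`D = (A − B) / sqrt(A + B)`, where A and B are total reference and
alternate reads over heterozygous individuals — the binomial(0.5) z-score of
the read split. Collapsed duplicate loci show excess H and |D|; the default
cut-offs are H > 0.55 or |D| > 5. SNPs with no heterozygotes have D = 0 and
are retained. Duplicate samples are flagged with the Yang genomic-relatedness
estimator `A_jk = mean_snps (x_j − 2p)(x_k − 2p) / (2p(1−p))` restricted to
MAF ≥ 0.05 (rare alleles bias the estimator upward), flagging pairs above
0.9. Note the estimator uses sample allele frequencies and is biased downward
on very small panels; it is intended for datasets with tens of samples or
more. Missing genotypes are excluded pairwise (never imputed) in both H/D and
relatedness, matching the common command-line tools' behavior.

## Diversity and differentiation

Per population we report mean expected heterozygosity (the unbiased
`2p(1−p)·2n/(2n−1)` per SNP), mean observed heterozygosity, and
`F_IS = 1 − mean(H_O)/mean(H_E)` computed from the population means — the
summary-file convention of the STACKS `populations` module, which differs
from averaging per-SNP F_IS. Means are taken over SNPs polymorphic in the
dataset; a population monomorphic at every SNP gets missing F_IS.

Differentiation is the Weir–Cockerham (1984) estimator: per-SNP variance
components a (among populations), b (among individuals within populations)
and c (within individuals), combined as the ratio of sums
`θ = Σa / Σ(a+b+c)` across loci (the "weighted" estimator reported by
Arlequin, hierfstat and PLINK). Monomorphic SNPs contribute zero to both
sums; negative estimates are reported as-is, since slightly negative θ (and
the negative F_IS typical of outbred fish populations) is informative.
Pairwise significance uses label permutations of individuals between the two
populations with `p = (1 + #{θ* ≥ θ}) / (n_perm + 1)` (the +1 correction
avoids p = 0) and Bonferroni correction across pairs.

## Isolation by distance

In-water distances come from Dijkstra shortest paths on a lattice over a
binary land/water resistance raster (land impassable, water cost 1), with
8-neighbor connectivity and √2 diagonal weighting by default (4 and 16 are
available). Distance units are raster cell units; no geodesic correction is
attempted. IBD is the OLS regression of linearized F_ST, `θ/(1−θ)`, on
in-water distance, with significance from a one-sided (positive-association)
Mantel permutation test — the same orientation as the vegan default. The
Mantel implementation is cross-checked against `vegan::mantel` in the test
suite.

## Genome scan

The scan follows the pcadapt construction with current best practice of
neutral parameterization: principal components are estimated on an LD-thinned
SNP set, the test is applied to all SNPs.

1. **Thinning** (`ld_clump_thin()`): greedy clumping visits SNPs in
   decreasing-MAF order; each visited SNP removes unvisited neighbours within
   a 50-SNP window whose squared dosage correlation exceeds 0.2. Iterative
   pruning then removes contiguous intervals of PC-loading outliers
   (|loading| > 6 MADs from the per-PC median, runs of ≥ 3 SNPs) and repeats
   to convergence — an approximation of the long-range-LD removal of
   `snp_autoSVD`, not a bit-for-bit reproduction. Whether the 0.2 threshold
   is on r or r² is ambiguous in common usage; we follow the r² semantics
   and expose it as configuration.
2. **K selection** (`choose_k_scree()`): the bulk eigenvalue spectrum of an
   unstructured sample declines in small, even relative steps, so genuine
   structure appears as a large relative gap. We pick the largest K whose
   relative eigenvalue drop `(λ_K − λ_{K+1})/λ_{K+1}` exceeds both 3× the
   median relative drop and an absolute floor of 0.05. On simulations this
   returns K = number of demes − 1 for well-separated structure and K = 1
   under panmixia. A user override always wins and is recorded.
3. **Test statistic** (`pcadapt_scan()`): each SNP (MAF ≥ 0.05) is regressed
   on the K orthonormal score vectors; the K-vector of regression z-scores
   is summarized by its robust squared Mahalanobis distance, using the MCD
   scatter with the standard one-step reweighting (trim at χ²₀.₉₇₅, rescale
   by the trimming consistency factor — the raw MCD scatter is biased low,
   which would inflate the genomic inflation factor by ~15%). The genomic
   inflation factor `λ = median(D²)/χ²_K(0.5)` divides D² before the
   χ²_K upper tail, and λ is reported so inflation can be audited. Missing
   genotypes are mean-imputed only inside this computation.
4. **FDR**: Storey q-values (smoother π₀ estimate over the λ-grid
   0.05–0.95) when at least 100 p-values are available, otherwise
   Benjamini–Hochberg (π₀ = 1). Outliers are SNPs with q < 0.01.

Region-specific scans (`run_pipeline()` scopes) re-thin and re-select K
within each sample subset, and outlier sets are combined as a union with
per-SNP scope provenance, since fine-scale signals can be masked by the
dominant structure in the full dataset.

## Genomic islands of divergence

Outlier flags are scanned in windows of 250 SNPs stepped by 50 (SNP ordinal
space, per chromosome; chromosomes shorter than one window are skipped and
logged). Windows with ≥ 10 outliers are candidates; overlapping-or-adjacent
candidates merge, and a gap of at least one non-candidate window breaks a
region. Each merged region is trimmed to its outermost outlier positions so
the reported span does not depend on window size. Regions are characterized
by pairwise θ on the region's outliers with a percentile bootstrap over loci
(1,000 resamples; significant if the 95% CI excludes zero), a one-sided
paired Wilcoxon test of region θ against genome-wide θ over the same
population pairs (exact for ≤ 25 pairs), and the population × SNP
alternate-allele-frequency matrix.

## LD analysis

r² is the squared Pearson correlation of dosages over individuals called at
both SNPs — the composite measure PLINK computes on unphased genotypes; no
haplotype-EM r² (and no D′) is attempted. Eligibility filters (MAF ≥ 0.01,
≥ 400 bp spacing) apply to both the empirical set and the permutation null:
each of 10,000 iterations draws an equally sized random SNP set from the same
chromosome under the same filters, so target and null sets are exchangeable.
The test statistic is the mean pairwise r² among targets; the choice of
summary is configurable since different summaries (min, median) emphasize
different block structures. The chromosome-wide block finder flags SNPs whose
mean r² to their 10 nearest neighbours on either side exceeds 0.2 (taking
the better of the forward/backward neighbourhoods so block-edge SNPs are not
diluted), bridges gaps of up to 5 unflagged SNPs, and reports runs spanning
more than 1 Mb.

## Inversion screen

`local_pca_mds()` cuts a chromosome into non-overlapping 50-SNP windows,
summarizes each window by the rank-2 approximation of its individual
covariance scaled to unit Frobenius norm, takes pairwise Frobenius distances
between windows (the lostruct construction in spirit, not in bit-for-bit
numerics), embeds them with classical MDS (up to 40 axes), and flags windows
whose MDS1 coordinate is more than 3 SD from the mean. Flagging on MDS1 only
is the default because the leading axis is where inversion-like windows
separate; scanning further axes is configurable. A useful design fact: with
k of n windows sharing an extreme coordinate, the largest attainable
standardized excursion is `sqrt((1 − k/n)(n − 1)/k)`, so the 3-SD rule can
only fire when the atypical windows are a modest fraction of the chromosome
(≈ ≤ 8% for 100 windows). That matches the intended use — screening an ~8 Mb
block on a ~60 Mb chromosome — and is why the synthetic recovery tests use
chromosomes with ≥ 60 windows. The flagging threshold is interpreted on MDS
coordinates rather than raw eigenvector loadings; both readings exist in the
literature and the coordinate reading matches how such screens are plotted.

`genotype_cluster_pca()` clusters individuals on (PC1, PC2) of the candidate
region's genotypes with k-means (25 seeded restarts), choosing k ∈ {2, 3} by
mean silhouette width — 3 clusters is the canonical inversion pattern, but a
rare minor haplotype may show only 2 (no minor homozygotes sampled). Clusters
map to inversion genotypes as follows: for k = 3 the PC1-extreme clusters are
the homozygotes (the larger one is C0) and the middle is the heterozygote C1;
for k = 2 the cluster with the higher mean observed heterozygosity across the
region SNPs is C1 and C2 = 0. Haplotype frequency is
`F = (2·C_hom + C_het) / (2N)` per population and overall, with haplotypes
named major/minor by overall frequency (without an outgroup or assembly
comparison, ancestral vs derived cannot be determined).

## Synthetic data

The generator is a hierarchical Balding–Nichols allele-frequency model:
ancestral frequencies Uniform(0.05, 0.95); regional-group frequencies drawn
around them with differentiation `fst_region`; deme frequencies around those
with `fst_deme`; genotypes Hardy–Weinberg within demes; independent
missingness; negative-binomial read depths with Binomial(0.5) heterozygote
splits. With `fst_region = 0` this is a single-level island model whose
expected multi-locus θ equals `fst_deme`, which the tests verify against the
Weir–Cockerham estimator. A coalescent backend was considered and not built:
no coalescent simulator is available in this R stack, and the only feature it
would add — realistic background LD — is supplied where needed by explicit
haplotype-block injection. Consequently background SNPs are in linkage
equilibrium, which makes the LD-thinning stage lighter-touch than on real
data; the clumping and long-range-LD logic is exercised instead by injected
blocks.

Defaults mirror the study system the package is designed around: 17 demes in
two weakly diverged regional groups (`fst_deme = 0.0035`,
`fst_region = 0.003`, giving overall weighted θ in the 0.005–0.01 band),
divergence islands of a few Mb with island θ ≥ 5× background, and one
~8.4 Mb non-recombining haplotype block at frequency 0.096 with no minor
homozygotes. Islands are injected by shifting affected/unaffected deme
frequencies to `p̄ ± sqrt(F·p̄(1−p̄))`, which targets a parametric two-group
F_ST of F. The inversion injects two non-recombining haplotypes with
near-fixed differences (alternate-allele frequency 0.95 on the minor
haplotype vs 0.03 on the major) at 85% of span SNPs — the fraction that
reproduces a block-wide mean r² near 0.3 at a 10% haplotype frequency; when
minor homozygotes are disallowed, carrier status is drawn heterozygous with
probability 2f, which preserves the expected haplotype frequency exactly,
and the realized carrier frequency is recorded in the truth manifest. The
procedural raster is a generic two-armed lake with a peninsula barrier —
topology, not geography.

What passing tests on this generator do *not* show: robustness to background
LD, to genotyping-error structure correlated with depth, to non-equilibrium
demography (bottlenecks, admixture clines), or to the STACKS assembly
artifacts the HDPlot filter targets (the AD simulator can mimic paralog-like
read-ratio bias, but real paralog collapse is messier).

## Problem sizes and numerical choices

The test suite and the acceptance script run deliberately scaled-down
problems chosen to keep the full suite in the minutes range while leaving
each statistical check well-powered: null calibration uses 100 individuals ×
5,000 SNPs (one scan) and 200 seeded permutation runs of 99 permutations
each; recovery uses 20 replicates of 120 individuals × 2,400 SNPs with one
injected island, and one 200–340-individual inversion dataset with a
60-window chromosome. Permutation p-values always use the +1 correction;
bootstrap CIs are percentile with recorded seeds; SVDs use base LAPACK;
MCD failures (singular scatter) fall back to a median/MAD diagonal with a
warning; zero-variance SNPs yield missing r² rather than 0; ties in k-means
are broken by 25 restarts under a recorded seed.

## Known limitations

Multiallelic sites and phased haplotypes are out of scope; ADMIXTURE-style
ancestry estimation, AMOVA, effective-population-size estimation and
genotype–environment association are deliberately not implemented; the
least-cost engine assumes a planar grid (no projection handling); and the
inversion screen diagnoses *putative* inversions only — confirmation needs
long-read assemblies or karyotyping.
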