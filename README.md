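# radpopgen

Population genomics of RAD-capture (Rapture) SNP data: quality control,
population structure and diversity, isolation by distance over in-water
least-cost paths, PCA genome scans with sliding-window detection of genomic
islands of divergence, linkage-disequilibrium permutation tests, and a
local-PCA screen for putative chromosomal inversions — with a synthetic-data
generator carrying ground-truth manifests so every stage can be validated.

The package is aimed at fisheries and conservation genomicists working with
dense reduced-representation SNP panels on weakly structured wild populations
(the motivating system is lake whitefish, *Coregonus clupeaformis*, in Lake
Michigan: 17 spawning populations, genome-wide F_ST below 0.01, yet sharply
localized islands of adaptive divergence and a low-frequency putative
inversion).

## What it computes

- **QC cascade** (`filter_cascade`, `hdplot_filter`, `relatedness_dedup`,
  `thin_by_distance`, `haplotype_count_filter`): minor-allele-count, call
  rate and individual-missingness filters in a fixed auditable order; the
  HDPlot paralog screen `D = (A − B)/√(A + B)` on pooled heterozygote read
  depths; Yang-relatedness duplicate flagging; distance and RAD-tag thinning.
- **Diversity and differentiation** (`diversity_stats`, `wc_fst`,
  `pairwise_fst`, `fst_permutation_test`, `linearize_fst`): H_E, H_O,
  F_IS = 1 − H_O/H_E per population; Weir–Cockerham (1984) θ as the
  ratio of summed variance components, `θ = Σa / Σ(a+b+c)`, with
  label-permutation significance and Bonferroni correction.
- **Isolation by distance** (`least_cost_distances`, `mantel_test`,
  `ibd_regression`): Dijkstra least-cost paths over a binary land/water
  raster; OLS of θ/(1−θ) on in-water distance; one-sided Mantel permutation
  test.
- **Genome scan** (`ld_clump_thin`, `choose_k_scree`, `pcadapt_scan`,
  `compute_qvalues`, `combine_outlier_sets`): PCs from an LD-thinned SNP
  set; per-SNP K-vector of regression z-scores summarized by a robust
  Mahalanobis D², calibrated by the genomic inflation factor
  λ = median(D²)/χ²_K(0.5) and referred to the χ²_K tail; Storey/BH
  q-values; outliers at q < 0.01; unions across full/regional scopes.
- **Islands of divergence** (`sliding_window_scan`, `merge_and_trim_regions`,
  `region_fst_ci`, `region_vs_genome_test`, `region_allele_frequencies`):
  250-SNP windows stepped by 50, candidates at ≥ 10 outliers, merged and
  trimmed to the outermost outliers; bootstrap CIs on region θ; paired
  one-sided Wilcoxon region-vs-genome; per-population allele frequencies.
- **LD** (`pairwise_r2`, `ld_background_permutation`, `ld_heatmap_matrix`):
  dosage-correlation r²; permutation test of mean r² among target SNPs
  against same-chromosome random draws under matched filters; extended-LD
  block detection.
- **Inversion screen** (`local_pca_mds`, `genotype_cluster_pca`,
  `haplotype_frequency`, `genotype_heatmap_export`): windowed local PCA with
  MDS embedding and 3-SD flagging on MDS1; k-means genotype clustering on
  (PC1, PC2) with silhouette-chosen k ∈ {2, 3}; haplotype frequency
  `F = (2·C_hom + C_het)/(2N)`.
- **Synthetic data** (`sim_config`, `simulate_dataset`,
  `inject_divergence_island`, `inject_inversion`,
  `simulate_raster_and_coords`, `write_sim_dataset`): hierarchical
  Balding–Nichols demes, injected islands and non-recombining haplotype
  blocks, procedural two-armed lake rasters, JSON truth manifests.
- **Pipeline** (`run_config`, `define_scopes`, `run_pipeline`): config-driven
  orchestration of all stages with regional scopes, stage skipping and
  TSV/BED/JSON outputs. A thin command-line wrapper lives at
  `inst/cli/radpopgen.R`.

## Worked example

```r
library(radpopgen)

cfg <- sim_config(n_pops = 8, n_ind = 25, n_chrom = 3, snps_per_chrom = 3000,
                  chrom_length_bp = 60e6,
                  islands = list(list(chrom = "chr01", start_bp = 20e6,
                                      end_bp = 24e6, fst = 0.2,
                                      affected_pops = NULL)),
                  inversion = list(chrom = "chr03", start_bp = 30e6,
                                   end_bp = 34.5e6, f = 0.10,
                                   allow_minor_homozygotes = FALSE),
                  seed = 7)
sim <- simulate_dataset(cfg)
x <- filter_cascade(sim$data)$data
x
#> geno_set: 200 individuals x 9000 SNPs
#>   populations: 8
#>   chromosomes: 3
#>   allele depths: present

round(wc_fst(x)$theta, 4)          # background weighted F_ST
#> [1] 0.0092

thin <- ld_clump_thin(x)
K <- choose_k_scree(x, thin$keep)$K
scan <- pcadapt_scan(x, thin = thin$keep, K = K, seed = 7)
scan
#> scan_result (scope full): K = 1, lambda = 1.113, 179 outliers / 8865 tested SNPs

regions <- merge_and_trim_regions(
  sliding_window_scan(scan$table$outlier, x$snps, 250, 50, 10),
  scan$table$outlier, x$snps)
regions[, c("chrom", "start_bp", "end_bp", "n_outliers")]
#>   chrom start_bp   end_bp n_outliers
#> 1 chr01 20014477 23972819        178

lp <- local_pca_mds(x, "chr03")
lp
#> local_pca_map: 60 windows, 4 flagged
#>   flagged span: 30228022 - 34280094 bp

ids <- with(x$snps, id[chrom == "chr03" & pos >= lp$flagged_span[1] &
                         pos <= lp$flagged_span[2] & maf >= 0.05])
cl <- genotype_cluster_pca(x, ids, seed = 7)
cl
#> genotype_clusters: k = 2 | C0 = 161 C1 = 39 C2 = 0

hf <- haplotype_frequency(cl)
round(subset(hf, population == "overall")$f_minor, 3)
#> [1] 0.098
```

Reading the output: the genome-wide weighted θ of 0.0092 is the weak
background differentiation typical of high-gene-flow lake populations. The
scan (K = 1 axis of structure, inflation factor 1.113) flags 179 outliers
that the window rule condenses into one candidate region at 20.0–24.0 Mb on
chr01 — the injected island, recovered edge to edge. On chr03 the local-PCA
screen flags 4 consecutive windows (30.2–34.3 Mb) whose population structure
departs from the chromosomal background; genotypes there fall into two PC1
clusters (no minor-haplotype homozygotes) and the estimated minor-haplotype
frequency is 0.098 against a simulated truth of 0.10.

## Vignette

`vignettes/radpopgen-methods.Rmd` documents the statistical models, default
parameters with their rationale, numerical decisions, what the synthetic
generator does and does not emulate, and known limitations.
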