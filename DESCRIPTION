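Package: radpopgen
Title: Population Genomics of RAD-Capture SNP Data: QC, Structure,
    Genome Scans, Divergence Islands and Inversion Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for reduced-representation (RADseq /
    Rapture) SNP datasets from wild populations: VCF import and a
    configurable quality-control filter cascade (minor allele count, call
    rate, individual missingness, paralog detection from read-ratio
    deviation, relatedness-based duplicate removal, haplotype-count and
    distance thinning); per-population diversity and Weir-Cockerham
    F_ST with permutation significance; isolation-by-distance over
    in-water least-cost paths with Mantel tests; a principal-component
    Mahalanobis genome scan with genomic-inflation correction and
    q-values; sliding-window detection and characterization of genomic
    islands of divergence; linkage-disequilibrium permutation tests; a
    local-PCA/MDS screen for putative chromosomal inversions with
    genotype clustering and haplotype-frequency estimation; and a
    synthetic-data generator with ground-truth manifests for validating
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    vcfR,
    igraph,
    MASS,
    cluster,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
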