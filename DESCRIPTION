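Package: haploscan
Title: Haploblock Inference, Mixed-Model GWAS and Haploblock Set Enrichment
    for Selfing Crop Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for landrace-scale genetic analysis of predominantly
    selfing crops: reading and filtering biallelic SNP panels from VCF,
    linkage-disequilibrium characterization (pairwise dosage r-squared,
    unlinked critical values, LOESS decay range), confidence-interval
    haploblock partitioning from |D'| likelihoods, single-locus linear
    mixed-model GWAS with population-structure covariates and genomic
    control, a GSEA-style haploblock enrichment test over SNP rankings
    with a permutation null, and Dice-similarity bi-clustering of traits
    by their shared enriched haploblocks. Includes a synthetic-data
    generator with planted founder-haplotype blocks, group structure,
    correlated bioclimatic covariates and ground truth for recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    geosphere,
    jsonlite,
    vcfR
Suggests:
    ape,
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
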