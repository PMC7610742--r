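Package: gwaspeaks
Title: Multi-Phenotype GWAS Peak Extraction and Cross-Phenotype Locus
    Clustering with X-Chromosome Support
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for running many genome-wide association scans over
    large phenotype panels and aggregating the results into loci. Implements
    rank-based phenotype cleaning (median-absolute-deviation outlier masking,
    Blom quantile normalisation, confound residualisation, discovery/replication
    splitting), sex-aware variant quality control (minor allele frequency,
    imputation INFO score, female-only Hardy-Weinberg exact testing on
    chromosome X), per-variant linear association with dosage-compensation
    coding of male X genotypes, greedy per-phenotype peak extraction and
    cross-phenotype cluster aggregation in centimorgan space via binary
    max-heaps, replication and Bonferroni annotation, and sex-stratified
    Fisher meta-analysis. Ships a synthetic cohort simulator with planted
    effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
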