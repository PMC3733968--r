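Package: pathsnpset
Title: Pathway SNP-Set Association Testing with Pedigree Mixed Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tests whether the SNPs surrounding the genes of a biological
    pathway are collectively associated with quantitative traits, using a
    random-gene-set permutation strategy developed for livestock gene-set
    studies.  Per-SNP effects are estimated with a linear mixed model that
    controls population structure through the pedigree-derived numerator
    relationship matrix (REML variance components via a single spectral
    decomposition of the kinship matrix).  The package builds flanked gene
    windows, assigns SNPs to windows, computes the proportion-significant
    statistic for a SNP set, derives experiment-wise significance from
    random gene sets, reports the m*P/S false discovery rate, quantifies
    pleiotropy through correlations of per-SNP effect estimates across
    traits, and ships a synthetic-data generator (multi-generation
    pedigrees, LD-structured genotypes, correlated polygenic traits) so the
    whole pipeline is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
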