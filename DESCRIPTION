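Package: triorank
Title: Rank-Based Cross-Population Comparison of Trio GWAS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing genome-wide association signals across
    ancestrally diverse cohorts of affected-offspring trios without relying
    on a uniform significance threshold. Implements the transmission
    disequilibrium test (TDT) with standard SNP quality control, rank-based
    top-n SNP and gene overlap between populations with closed-form chance
    expectations, pathway over-representation of noteworthy genes with a
    gene- or SNP-resampling empirical null, per-SNP fixation-index (FST)
    estimation, and a chi-square test of dependence between population
    differentiation and cross-population differences in association rank.
    Includes a Balding-Nichols trio-cohort simulator with planted
    transmission-distorted risk SNPs so that every stage of the pipeline can
    be exercised and calibrated on data with known structure. Reads and
    writes PLINK text PED/MAP, BED gene annotations, and GMT gene sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
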