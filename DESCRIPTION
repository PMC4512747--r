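Package: pleioscan
Title: Cross-Trait Polygenic Concordance, Summary-Statistic Risk Scores,
    and Bivariate GREML
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Three-arm analysis of shared genetic liability between a
    quantitative discovery trait and a case-control target trait from GWAS
    summary statistics and genotype panels: sign-concordance scanning with
    an exact binomial test across P-value inclusion thresholds, polygenic
    joint-effect estimation from summary statistics (precision-weighted
    mean of per-SNP effect ratios), and SNP-heritability / genetic
    correlation estimation by average-information REML on genomic
    relationship matrices. Includes P-value ranked LD clumping against a
    reference dosage panel, Nyholt effective-number-of-tests correction,
    allele harmonization of summary tables, and a liability-threshold
    simulator of paired GWAS studies with known heritabilities and genetic
    correlation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
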