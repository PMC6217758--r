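Package: mqtlpipe
Title: Methylation QTL Mapping, Colocalization, and Summary-Based
    Mendelian Randomization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pipeline linking common genetic variants, DNA
    methylation, gene expression, and complex traits: covariate-adjusted
    genome-wide mQTL scanning with a fast matrix implementation equivalent
    to per-pair ordinary least squares, greedy LD clumping of association
    signals, pairwise Bayesian colocalization of CpG mQTL profiles using
    approximate Bayes factors, two-stage SMR (Wald-ratio) tests with the
    HEIDI heterogeneity filter for CpG-trait and CpG-expression designs,
    and annotation-enrichment statistics. Includes a seeded synthetic-data
    generator with known ground truth (LD-block genotypes, beta-scale
    methylation with planted cis and trans effects, confounded covariates,
    independent GWAS and eQTL cohorts) so that every stage is testable
    end to end without access to controlled cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    vcfR,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
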