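Package: hipower
Title: Heritability-Informed Power Optimization for Multi-Trait GWAS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint association analysis of genetically correlated traits from
    genome-wide association study (GWAS) summary statistics. Estimates the
    genetic covariance and the sampling covariance of effect estimates by
    cross-trait LD-score regression, derives orthogonal linear combinations of
    per-SNP effect estimates that maximize the average non-centrality parameter
    of the association chi-square statistic, and tests each SNP along these
    components. Includes an MTAG-style moment estimator for comparison, a
    direct simulator of multi-trait summary statistics with linkage
    disequilibrium, sample overlap and population stratification, and
    post-processing utilities (LD clumping, novel-locus calling, type-I-error
    and genomic-inflation metrics).
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
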