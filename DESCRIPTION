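Package: metgxe
Title: Genotype-by-Environment and QTL-by-Environment Analysis for
    Multi-Environment Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of multi-environment trials (METs) of clonally
    replicated plant populations, motivated by flowering-time genetics in
    sweet cherry.  Provides a restricted maximum likelihood (REML) mixed
    model engine for genotype-by-environment models with structured
    genetic and residual covariances, between-environment genetic
    correlations, broad-sense heritabilities of clonal means, fixed-effect
    QTL and QTL-by-environment models with Wald tests, least-squares means
    with pairwise contrasts, phenotype and climate descriptives, and a
    synthetic full-sib F1 MET generator with truth records for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    stats,
    utils
Suggests:
    emmeans,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
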