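Package: triomr
Title: Family-Based Mendelian Randomization with Parent-Offspring Trios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for family-based Mendelian randomization (MR) analyses of
    prenatal exposures on offspring outcomes. Simulates parent-offspring trio
    genotypes under Hardy-Weinberg equilibrium with Mendelian transmission and a
    hurdle-structured maternal exposure; derives exposure and outcome phenotypes
    (scale-score mean imputation, rank-based inverse normal transformation,
    PCA-based effective number of tests); builds weighted and unweighted
    polygenic score instruments with strength diagnostics; fits observational
    models with a paternal negative control; runs individual-level conditional
    MR in mother-child duos and parent-offspring trios (optionally with a
    genomic-relationship-matrix mixed model) and gene-by-environment stratified
    MR; implements two-sample MR estimators (IVW, MR-Egger, weighted median,
    simple and weighted mode, multivariable IVW) with heterogeneity and
    pleiotropy diagnostics; and partitions maternal and offspring genetic
    effects into direct effects with overlapping-sample covariance.
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
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
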