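Package: dcisatlas
Title: Multi-Region Genomic and Immune Micro-Environment Analysis of Breast Pre-Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for multi-region molecular profiling of ductal
    carcinoma in situ (DCIS) and related pre-invasive breast lesions. Provides
    joint multi-region piecewise-constant segmentation of bin-level log2 copy
    ratios, bin-weighted copy-number divergence between regions, copy-number
    burden, ternary discretization of segment calls, exhaustive maximum-parsimony
    phylogeny reconstruction rooted at a diploid ancestor, a tumor-only somatic
    variant filtering cascade with pool-of-normal and hotspot-rescue rules, a
    Bayes-factor multi-region variant presence caller, non-negative matrix
    factorization of compartmentalized immune-cell densities into meta-markers
    with immune-state assignment, the supporting statistics (conditional-MLE
    odds ratio, Mann-Whitney U, OLS), and seeded synthetic-data generators that
    plant known truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ape,
    phangorn,
    mclust,
    vcfR,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
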