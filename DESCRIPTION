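Package: mediassoc
Title: Genetic Association, Smoking-Mediated Risk and Meta-Analysis for
    Case-Control Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding whether a genetic risk variant acts on
    disease directly or indirectly through a behavioural exposure.
    Implements case-control association statistics from genotype count
    tables (crude and per-allele odds ratios, Cochran-Armitage trend
    tests, Hardy-Weinberg checks, covariate-adjusted logistic models,
    analytic power), genotype-exposure analyses of smoking intensity and
    age-of-onset trends, a Doll-Peto dose-response mediation calculation
    translating genotype-associated shifts in cigarettes per day and
    smoking duration into predicted relative risks, population
    attributable risk for one or several loci, a liability-threshold
    model of familial risk attributable to a heritable exposure, a
    fixed/random-effects meta-analysis engine with heterogeneity and
    Egger small-study diagnostics, and a synthetic cohort simulator so
    every stage of the pipeline can be exercised without access to the
    original individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    MASS,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
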