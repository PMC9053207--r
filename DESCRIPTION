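Package: tmbsite
Title: Biopsy-Site Effects on Tumor Mutational Burden
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for pan-cancer analysis of how biopsy site
    associates with tumor mutational burden (TMB): specimen selection and
    quality filtering, TMB scoring from variant calls, per-cancer
    covariate-adjusted linear models on log(TMB+1) with estimated-marginal-mean
    site contrasts back-transformed to mut/Mb by the delta method, dichotomous
    TMB-high comparisons (odds ratios, chi-square), metastasis-history
    controlled stratification, and exact paired-biopsy testing. Includes a
    reproducible synthetic clinico-genomic cohort generator with a
    ground-truth effect table for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    vcfR,
    withr
Config/testthat/edition: 3
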