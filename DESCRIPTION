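Package: hteforest
Title: Honest Causal Forests for Heterogeneous Effects in Matched Register Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying heterogeneous treatment effects in large matched
    register-style cohorts, built around a from-scratch honest causal forest with
    gradient (pseudo-outcome) splitting, local centering by out-of-bag regression
    forests, augmented inverse probability weighted (AIPW) average effects, pilot-forest
    covariate screening, cross-fitted CATE quartile ranking, and standardized
    mean difference profiling of the most and least affected groups. Includes a
    calibrated synthetic cohort generator emulating a Finnish full-population
    childhood type 1 diabetes study design (stratified matching on region, sex and
    birth year; censored and top-coded outcomes; configurable ground-truth effect
    heterogeneity) so that the whole pipeline can be validated against known truths.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    ranger,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
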