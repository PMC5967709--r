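Package: founderisk
Title: Founder-Population Allele Enrichment and Disease-Risk Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Statistical toolkit for genetic epidemiology in bottlenecked
    (founder) populations. Scores per-variant allele-frequency enrichment of a
    study population against reference populations using bias-corrected
    (Haldane-Anscombe) log odds ratios and one-sided Fisher exact tests;
    performs Firth penalized case-control logistic regression and Bayesian
    cross-study meta-analysis with Wakefield approximate Bayes factors under
    correlated- and independent-effects models; models composite-carrier
    (1-hit/2-hit) non-additivity; decomposes polygenic risk score differences
    between populations into per-variant contributions; and translates
    risk-score shifts into expected disease-prevalence ratios under logit and
    probit liability models. Includes sample/variant quality-control and
    ancestry-assignment filters and synthetic-data generators for every input
    the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR
Config/testthat/edition: 3
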