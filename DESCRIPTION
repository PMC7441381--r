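Package: polypen
Title: Polygenic Background Modification of Monogenic Disease Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint modelling of rare monogenic risk variants and polygenic
    scores for common disease. Computes polygenic scores from effect-allele
    dosages, ancestry-corrects them by principal-component residualization,
    derives percentiles and score strata; applies allele-frequency,
    consequence and region quality filters to annotated variants and calls
    monogenic carrier status; fits stratified and interaction logistic
    models for disease odds and Cox models on the age scale for cumulative
    incidence (penetrance) by age 75; and estimates retrospective power for
    carrier-by-score interaction tests by conditional-Bernoulli phenotype
    simulation with the case total held fixed, including detectable
    odds-ratio bounds at a target power. Includes a synthetic-cohort
    generator with ancestry-structured genotypes, rare carrier variants,
    logistic prevalence and Weibull onset models for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
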