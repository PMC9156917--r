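Package: clinemap
Title: Geographic Cline Analysis of Dominance-Scored Colour Polymorphism Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing geographic variation in Mendelian colour
    polymorphism from georeferenced occurrence records scored into dominant
    and recessive phenotype classes. Records are aggregated into
    latitude/longitude grid cells, allele frequencies are estimated under
    Hardy-Weinberg equilibrium from the recessive-homozygote class, grid
    cells are projected onto great-circle transects using cross-track and
    along-track distances, and one-dimensional sigmoid cline models with
    optional exponential tails and frequency scaling are fitted by maximum
    likelihood and Metropolis MCMC with corrected-AIC model comparison.
    Morph-frequency associations with environmental covariates are tested
    with weighted regression screens, variance inflation factors, and
    generalized least squares with an exponential spatial correlation
    structure. A synthetic record generator with known clinal structure
    supports end-to-end validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    car,
    geosphere,
    nlme,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
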