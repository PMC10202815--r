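Package: couplemr
Title: Cross-Partner Mendelian Randomization in Couple Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and estimation toolkit for studying phenotypic partner
    similarity with cross-partner Mendelian randomization (MR). Simulates couple
    cohorts under a structural model with direct assortment on genotype,
    environment and trait, parental (dynastic) effects on the offspring
    environment, and within-person causal trait networks; emulates GWAS summary
    statistics; implements inverse-variance-weighted and multivariable MR with
    Steiger directionality and sex-heterogeneity instrument filters; decomposes
    couple trait correlations into causal and confounded components; decomposes
    cross-trait cross-partner effects into exposure- and outcome-assortment
    paths; and evaluates the closed-form bias of the cross-partner MR estimator
    under violations of the instrumental-variable assumptions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
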