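Package: warburgfba
Title: Constraint-Based Modelling of the Warburg Effect in Cell-Line Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Flux-balance modelling of aerobic glycolysis in cohorts of
    cell-line metabolic models. Builds expression-tailored models from a
    generic stoichiometric scaffold, quantifies forced lactate secretion and
    the glycolytic-to-oxidative ATP flux ratio (AFR) by sampling the
    maximal-biomass flux space, emulates bioenergetic dose-response
    experiments (ECAR/OCR), and runs a three-filter in-silico knockout
    screen for anti-migratory, growth-sparing metabolic targets. Includes
    hand-solvable fixture networks, a synthetic cohort generator with
    planted phenotype structure, and exact-permutation rank statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    xml2,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
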