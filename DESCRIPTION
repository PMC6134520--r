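Package: equidea
Title: Equity and Efficiency Analysis of Provincial Primary Health Care Resources
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to assess the equity and the efficiency of primary health
    care resource allocation across provinces from a province-by-year panel of
    populations, land areas and resource counts (institutions, beds, health
    workers). Equity is measured with Lorenz curves and weighted Gini
    coefficients, the Theil index with its within/between-region decomposition
    and contribution rates, and the health resource density index (geometric
    mean of per-capita and per-area densities). Efficiency and productivity are
    measured with input-oriented radial data envelopment analysis (CCR and BCC
    envelopment models with two-phase slack maximisation, returns-to-scale
    classification and projection targets) and the adjacent-period Malmquist
    productivity index with its full decomposition. A synthetic panel generator
    with known inefficiencies and known dispersion provides ground-truth
    recovery tests for every stage.
License: MIT
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
    pracma,
    optparse,
    withr
Config/testthat/edition: 3
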