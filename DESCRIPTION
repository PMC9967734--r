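Package: greenrisk
Title: Scenario Analysis of Green-Space Carbon Storage and Landscape Ecological Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools linking land-use policy scenarios to green-space carbon
    storage and landscape ecological risk on categorical land-cover rasters.
    Provides a seeded synthetic-landscape generator, Markov transition
    estimation with a suitability-constrained cellular-automaton projection
    under policy constraint rules, green-space evolution typing
    (expansion/exchange/loss), four-pool carbon bookkeeping, a grid-based
    landscape ecological risk index with ordinary kriging and natural-breaks
    classification, coupling-coordination scoring, and bivariate global/local
    Moran's I with permutation-based LISA clustering.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    nortest
Config/testthat/edition: 3
RoxygenNote: 7.3.3
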