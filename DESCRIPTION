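Package: herdghg
Title: Life-Cycle Greenhouse-Gas Accounting and Spatial Analysis for Livestock Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cradle-to-market accounting of livestock greenhouse-gas emissions
    (enteric fermentation, manure management, feed-grain cultivation and
    processing, feeding energy, product processing) for city-by-year panels,
    with CO2-equivalent aggregation under configurable global-warming
    potentials. Includes Theil-index inequality decomposition into within- and
    between-region components, Tapio decoupling elasticity with the eight-state
    classification, conventional and spatially conditioned Markov transition
    matrices of emission types, and a synthetic panel generator that emulates
    an 18-city, 5-region, 21-year provincial panel for testing and
    demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
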