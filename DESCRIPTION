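Package: landhab
Title: Land-Use Change, Landscape Pattern, and Habitat-Quality Modelling
    for Arid Landscapes
Version: 0.1.0
Authors@R:
    person("landhab", "developers", email = "landhab@example.org",
           role = c("aut", "cre"))
Description: Tools for monitoring and simulating land-use change and its
    consequences for habitat quality on categorical raster landscapes.
    Implements land-use dynamic degrees and transfer matrices, class- and
    landscape-level pattern metrics (NP, PD, LPI, LSI, AI, SPLIT, SHDI,
    CONTAG) computed from first principles, an InVEST-style habitat
    degradation and quality model with linear and exponential threat
    decay, the geographical-detector q-statistic with Jenks natural-breaks
    discretisation, and a Markov-demand cellular-automaton land-use
    simulator with patch seeding and kappa / figure-of-merit validation.
    Includes seeded synthetic-landscape generators so the whole pipeline
    is testable without external geodata, and a plain-text (ESRI ASCII
    grid) raster backend.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
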