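Package: islandSTR
Title: Species-Time Relationships and Assembly Processes for Island
    Community Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds species-time-relationship (STR) curves from island
    community presence/absence time series by three window algorithms
    (moving window, cumulative moving window, every possible window),
    fits power-law temporal scaling exponents S = c*T^w by log-log
    regression, computes Monte-Carlo Raup-Crick similarities against a
    regional-pool null model, classifies within-island census pairs into
    ecological processes (homogenizing dispersal, dispersal limitation,
    drift), and relates turnover and process frequencies to island size.
    Includes a neutral immigration-extinction simulator of a tree-hole
    archipelago sharing one regional taxon pool, so the full pipeline is
    exercisable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
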