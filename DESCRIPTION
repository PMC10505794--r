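Package: deepchron
Title: Consensus Node Calibrations, the Eukaryogenesis Interval, and
    Complexity Through Time on Timetrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deep-time comparative analysis on time-calibrated
    phylogenies. Builds consensus uniform calibration densities from
    filtered collections of published divergence-time estimates (literature
    screening rules plus a Student-t 99 percent confidence interval of the
    mean); combines posterior node-age summaries, fossil minima and the
    Great Oxidation Event into conservative and core eukaryogenesis
    intervals with fossil-margin and oxygen-gap diagnostics; performs
    maximum-likelihood ancestral state reconstruction and missing-tip
    imputation for continuous traits under Brownian motion via a two-pass
    pruning algorithm; and assembles a composite complexity metric (cell
    types, gene count, genome size) with through-time mean and smoothed
    moving-maximum curves. A seeded synthetic-data module (Yule trees,
    Brownian traits with optional clade shifts, masked observations,
    simulated published-time tables) supports fully reproducible analyses
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
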