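Package: gutwash
Title: Washout Modeling and Engraftment Analysis for Multi-Compartment
    Gut Fermentation Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing probiotic persistence experiments run in
    sequential in vitro colon bioreactors (SHIME-style ascending, transverse
    and descending compartments). Implements a discrete-cycle mechanistic
    dilution/washout model for a chain of stirred reactors with an optional
    per-compartment net-growth extension; absolute quantification of qPCR
    measurements via the genome-mass copy-number formula with baseline
    subtraction; engraftment inference that compares measured trajectories to
    the no-growth prediction, fits net growth multipliers and classifies
    per-compartment outcomes; community summaries (Shannon diversity,
    richness, Faith's phylogenetic diversity, Firmicutes/Bacteroidetes ratio,
    phylum aggregation) and short-chain fatty acid statistics (stratified
    Welch tests, Pearson taxon correlations); and a seeded synthetic-data
    generator producing qPCR trajectories, overdispersed feature tables,
    random trees and SCFA tables so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    picante,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
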