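Package: PombeCycleBN
Title: Threshold Boolean Network Models of the Fission Yeast Cell Cycle
    Oscillator
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A deterministic synchronous threshold Boolean network engine
    for gene regulatory models, built around the fission yeast
    (Schizosaccharomyces pombe) cell cycle core oscillator and its
    extension by Cdc2/Cdc13-driven phosphorylation events on the
    transcription factors Sep1, Fkh2, Atf1 and Cdc10. Provides S4 classes
    for networks, states, trajectories and attractors; simulation with
    phase-gated event rules; attractor detection and exhaustive
    basin-of-attraction enumeration; recovery of per-node threshold
    parameters from printed state trajectories; fold-enrichment arithmetic
    with an exact hypergeometric tail; a plain-text network format,
    trajectory TSV I/O and GraphML export; and a small command-line
    interface for running and validating the bundled model variants.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'netmodel.R'
    'engine.R'
    'rulefit.R'
    'models.R'
    'enrichment.R'
    'io.R'
    'cli.R'
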