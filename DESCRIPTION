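Package: bcdecode
Title: Temporal Decoding of the Bicoid Morphogen: Gap-Gene Circuit
    Simulation and MS2 Transcription-Spot Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the early Drosophila embryo decodes the
    Bicoid morphogen gradient in time. Implements a one-dimensional gap-gene
    gene-circuit model (hunchback, giant, Kruppel, knirps) driven by maternal
    inputs, with time-windowed deactivation of all Bicoid interactions to
    emulate optogenetic shutdown; scenario batteries, expression-boundary
    scoring against qualitative criteria, and parameter-ensemble z-scores.
    Also provides the accompanying quantification pipeline: MS2
    transcription-spot detection with regional contrast filtering,
    nearest-neighbour frame-to-frame linking, persistence filtering and
    regional statistics; morphogen-gradient extraction with exponential
    length-scale fitting and half-maximum boundary calling; ChIP-qPCR
    percent-input normalisation; and seeded synthetic-data generators so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml,
    minpack.lm,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
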