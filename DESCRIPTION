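Package: allokit
Title: Allosteric Signalling and Probing Maps from Coarse-Grained Protein Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes per-residue free-energy responses of a protein to
    point mutations and small-probe binding using a statistical-mechanical
    model built on a C-alpha elastic network. Assembles exhaustive
    Allosteric Signalling Maps (mutation scans) and Allosteric Probing Maps
    (three-residue probe scans), masks proximal and weak signalling into
    allosteric fingerprints, and applies a pLDDT-based quality filter for
    predicted (AlphaFold-style) structure models. Includes deterministic
    synthetic-structure generators so the whole pipeline is testable
    without external downloads, plus a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
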