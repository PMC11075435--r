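Package: dfmcyto
Title: Differential Fluorescent Marking Analysis for Flow-Cytometry
    Demultiplexing of Synthetic Bacterial Communities
Version: 0.1.0
Authors@R:
    person("DFM", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to simulate, gate and quantify combinatorially labelled
    bacterial strains measured by flow cytometry.  Six strain identities are
    encoded as presence/absence patterns of three fluorescent proteins
    (mCherry, sYFP2, mTagBFP) and demultiplexed with a fixed gating chain
    (Bacteria, Singlets, three colour populations, six exclusive Combined
    populations).  Gated counts are converted to absolute abundances on
    plant roots (events per mL, events per g root) with background
    subtraction from uninoculated plants.  Includes a seed-controlled
    event simulator with spectral spillover and autofluorescence, mean
    generation time estimation from plate-reader growth curves, community
    assembly summaries, and a Tn7 attB junction caller reporting the
    glmS-to-insertion offset and the 5-bp target-site duplication.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    optparse
Config/testthat/edition: 3
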