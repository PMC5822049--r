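Package: shapeproj
Title: Decomposing Transcription Factor Binding Models into Base and DNA Shape Readout
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing DNA shape readout by transcription factors.
    Implements parsimonious sequence-to-shape regression on k-mer shape
    tables (minor groove width, propeller twist, roll, helix twist),
    free-energy binding models with mononucleotide and adjacent-dinucleotide
    terms evaluated by transfer-matrix dynamic programming, penalized
    "shape projection" that decomposes a mechanism-agnostic binding model
    into base readout and position-specific shape-sensitivity profiles,
    complexity-matched random shape tables for empirical significance
    testing with Benjamini-Hochberg correction across binding-site
    positions, a desk-scale biophysical SELEX model fitter, and
    Metropolis-Hastings stratification of sequences by binding free energy.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
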