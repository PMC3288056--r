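Package: gcproteome
Title: Contamination-Corrected Spectral-Count Analysis of Growth Cone
    Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for turning label-free spectral-count tables of an
    isolated subcellular fraction (axonal growth cone particles) into a
    contamination-corrected net proteome. Implements calibration of a
    cytosolic-background multiplier from designated contaminant proteins,
    two-component background subtraction (plating-matrix control plus a
    scaled high-speed-supernatant fraction), semi-quantitative abundance
    profiles, over-representation statistics (EASE-style jackknifed Fisher
    tests, fold enrichment, Benjamini-Hochberg correction), kappa-based
    functional annotation clustering, proteome-versus-transcriptome overlap
    reports, and a synthetic-data generator with known ground truth for
    end-to-end validation.
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
    mclust,
    withr
Config/testthat/edition: 3
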