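Package: icmaldi
Title: Intact-Cell MALDI-TOF Consensus Spectra, Similarity Typing and
    Protein Peak Assignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for classifying microorganisms from intact-cell
    MALDI-TOF mass fingerprints. Builds replicate-consensus "virtual"
    reference spectra (peaks present in a minimum fraction of replicate
    acquisitions within an m/z tolerance), scores spectra against each
    other by the fraction of shared peak positions, renders all-pairs
    similarity heat maps and UPGMA similarity trees, and assigns
    candidate proteins to observed peaks from sequence-derived
    monoisotopic and average masses with and without the N-terminal
    methionine, including isoelectric-point calculation. A synthetic
    fingerprint and replicate-spectrum generator with controlled m/z
    jitter, peak dropout and spurious peaks supports end-to-end
    validation of every pipeline stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    ape,
    zoo,
    stats,
    utils,
    grDevices,
    pheatmap,
    Biostrings,
    mzR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
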