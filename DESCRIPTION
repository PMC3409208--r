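Package: pmfkit
Title: Peptide Mass Fingerprinting with Internal Calibration and
    Truncation Inference
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Protein identification from reflector-mode MALDI-TOF peptide
    mass fingerprints: in-silico tryptic digestion with fixed and variable
    residue modifications and missed cleavages, internal-standard mass
    recalibration, tolerance-based peak matching with ppm accuracy
    reporting, sequence-coverage and signal-fraction summaries,
    truncation-isoform inference from differential peptide evidence, a
    replicate two-dimensional-gel spot screen, and seeded synthetic
    spectrum generators for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    optparse,
    Biostrings,
    IRanges,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
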