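Package: retrodna
Title: Design and Quantification of Retron-Expressed Single-Stranded DNA Aptamers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Computational toolkit for expressing fluorogenic DNA aptamers from
    bacterial retrons. Provides structure-guided cargo-insertion design in the
    retron msd (a weighted base-pair maximisation folding engine with a
    pluggable external-engine interface, position classification, insertion-site
    ranking and fold-preservation scoring), comparative-CT qPCR quantification of
    RT-DNA abundance with per-cell copy number and intracellular concentration,
    global quadratic tight-binding isotherm fits of fluorogen titrations with
    residual-bootstrap confidence intervals, dilution-corrected RT-DNA half-life
    estimation from logistic growth and exponential decay fits, and seeded
    synthetic-data generators for every input so the full pipeline is testable
    offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    minpack.lm,
    jsonlite,
    Biostrings
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
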