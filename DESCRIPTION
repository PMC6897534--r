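Package: combokill
Title: Drug Combination Additivity and Cross-Resistance Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantitative analysis of multi-drug chemotherapy combinations:
    growth-rate (GR) normalization of dose-response checkerboards, Bliss
    independence (excess over Bliss) and Loewe additivity (isobologram and
    fractional inhibitory concentration) scoring, DNA-barcode clone-tracing
    enrichment with a scrambled-label error model, pooled CRISPRi/a screen
    phenotype and gene scoring, and estimation of the cross-resistance
    parameter xi that locates observed multi-drug resistance between its
    theoretical minimum (independent resistance) and maximum (full
    cross-resistance). Includes synthetic-data generators with known ground
    truth for every assay type so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    Biostrings,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
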