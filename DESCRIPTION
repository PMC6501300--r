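Package: cd8pdl1
Title: CD8xPD-L1 Predictive Signature Analysis for Immunotherapy Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for the CD8xPD-L1 predictive biomarker
    signature in non-small cell lung cancer immunotherapy. Quantifies CD8+
    and PD-L1+ cell densities (cells/mm2) from chromogenic IHC images by
    optical-density stain unmixing and object detection, computes the
    product signature (cells2/mm4), learns its positivity cutoff on a
    training cohort by maximizing positive predictive value under log-rank
    survival and prevalence constraints, evaluates stratification of
    overall survival, progression-free survival and objective response,
    and transfers the signature to an independent cohort by prevalence
    matching. A synthetic-data module generates patient cohorts and
    IHC-like images with known ground truth so every stage is testable
    without clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    png,
    jsonlite,
    withr,
    MASS
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
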