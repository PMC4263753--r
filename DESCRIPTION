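Package: refstab
Title: Reference-Gene Stability Selection and Efficiency-Corrected
    RT-qPCR Quantification
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Selection of stable reference genes for RT-qPCR data
    normalization and efficiency-corrected relative quantification of
    target genes.  Implements the geNorm gene-stability measure M with
    stepwise-exclusion ranking and pairwise-variation gene-count
    selection, the NormFinder model-based decomposition of intra- and
    inter-group expression variation, the BestKeeper descriptive
    dispersion statistics and index correlation, and a geometric-mean
    consensus ranking across the three algorithms.  Also provides
    dilution-series standard-curve fitting with slope/efficiency
    conversion, delta-Cq relative quantification with multi-gene
    normalization factors and fold-change reporting, and a synthetic
    quantification-cycle data generator with known ground-truth
    stability ordering for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
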