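Package: opcycle
Title: Cell-Cycle Kinetics of Oligodendrocyte Precursors from Labeling,
    Photobleaching and Peak-Enrichment Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimators and simulators for cell-cycle kinetics of
    oligodendrocyte precursor (OP) populations. Fits cumulative
    EdU-labeling time courses to recover total cell-cycle time and
    S-phase duration, corrects population-average estimates for
    incomplete Cre recombination (mixtures of recombined and
    unrecombined subpopulations), estimates G2 duration from
    pulse-chase labeled-mitoses counts, and derives G1 by subtraction.
    Fits FRAP and FLIP photobleaching traces (double plus full-scale
    normalization, single-exponential recovery) to extract histone
    mobile fractions and recovery half-times. Computes motif
    fold-enrichment with one-sided exact tests on differential
    ATAC peak sets and hypergeometric gene-set overlap tests. A seeded
    simulator generates every input the estimators consume:
    asynchronous steady-state cycling populations under labeling
    protocols, photobleaching traces with planted mobile fractions,
    and motif-annotated peak universes.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
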