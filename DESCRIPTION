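Package: oligoclamp
Title: Voltage-Clamp, Synaptic and Histology Quantification for Oligodendrocyte Precursor AMPAR Signalling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for AMPA-receptor-mediated signalling in
    oligodendrocyte precursors (OPs) and its consequences for oligodendrocyte
    numbers and myelin. Covers passive-membrane estimation and cell QC from
    whole-cell voltage-clamp probe transients, linearly scaled passive
    subtraction of voltage-gated Na+ currents, bath-agonist current
    quantification with series-resistance correction and rectification
    indices, EPSC threshold detection with frequency/amplitude summaries,
    paired-pulse and minimal-stimulation analysis, g-ratio and internode
    morphometry, and litter-normalized cohort statistics with a
    normality-gated test chooser and a step-down multiple-comparison
    correction. A conductance-based synthetic-data module simulates
    recordings and histology cohorts under genotype presets so every stage
    is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    signal,
    minpack.lm,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
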