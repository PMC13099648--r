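Package: hippex
Title: Hippocampal Excitability and Transcriptomic Candidate-Gene Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for studying early hippocampal
    hyperexcitability phenotypes across APOE genotypes and ages. Detects
    interictal spikes in local field potential recordings, extracts
    morpho-electric parameters (rheobase, output gain, spike latency,
    input resistance, membrane capacitance) from whole-cell current-clamp
    sweeps, classifies dentate granule cell subtypes by depolarization-block
    threshold, detects spontaneous synaptic currents by sliding-template
    matching and summarises the excitation-inhibition balance, clusters
    neurons into hyperexcitable and normal subpopulations with
    bootstrap-validated k-means and per-cell membership residuals, applies
    an age-by-genotype statistical framework (likelihood-ratio tests,
    FDR control, normality-routed post hoc tests, stratified association),
    and screens single-nucleus RNA-seq counts through a six-criterion
    multilevel candidate-gene filter with Jaccard-index cluster alignment.
    Every stage is exercisable on built-in synthetic data generators with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    signal,
    jsonlite,
    yaml,
    car,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
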