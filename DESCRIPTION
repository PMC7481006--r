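Package: ephyskit
Title: Cortical Microcircuit Electrophysiology: Excitability, Unitary
    Synapses, and Spike-Field Coupling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for patch-clamp and in vivo cortical
    electrophysiology. Provides current-clamp excitability analysis
    (passive membrane properties, action-potential features, logarithmic
    F-I curve fits with rheobase and gain), unitary synaptic-train
    analysis for paired recordings (per-pulse amplitudes, failure rates,
    charge transfer, short-term plasticity, pharmacological block
    ratios), and an in vivo spike/LFP pipeline (juxtacellular spike
    detection, spike-triggered LFP, band-wise pairwise phase
    consistency, and UP/DOWN cortical state segmentation by Gaussian
    mixture). Ground-truth simulators for two-state LFPs with
    phase-coupled spiking, leaky integrate-and-fire and logarithmic-rate
    current-step responses, and stochastic quantal synaptic trains make
    every analysis testable end to end, and cohort-level tools apply
    normality-gated two-group comparisons to the derived metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    mclust,
    minpack.lm,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllClasses.R'
    'AllGenerics.R'
    'cohort.R'
    'ephyskit-package.R'
    'filters.R'
    'intracellular.R'
    'invivo.R'
    'ppc.R'
    'simulate.R'
    'spectral.R'
    'states.R'
    'synaptic.R'
    'trace-io.R'
    'utils.R'
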