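Package: bulbnet
Title: Olfactory Bulb Microcircuit Simulation and Odor-Coding Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Compartmental Hodgkin-Huxley models of mitral, granule and
    periglomerular cells of the rodent olfactory bulb, wired into seeded
    stochastic network instances (random, directed, super-inhibitory
    "default", and slice variants) with dendro-dendritic reciprocal
    synapses. Includes synthetic olfactory receptor neuron drive (Gaussian
    odor kernels, m-sequence pulse trains, respiration waveforms,
    inhomogeneous Poisson spike trains), orchestrated stimulation
    protocols, and the odor-coding analyses built on them: linear-kernel
    fitting of firing-rate responses, residual-over-noise scores,
    respiration-phase and delta-rate decorrelation of sister mitral cells,
    and odor-morph model fitting. The cable integrator is implemented in
    C++ via Rcpp; analysis functions take and return tidy data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    generics,
    utils,
    stats,
    ggplot2,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
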