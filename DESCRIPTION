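Package: piriform
Title: Compartmental Modelling of NMDA-Spike Integration in Piriform
    Cortex Pyramidal Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates synaptic integration in the apical dendritic tree of
    olfactory (piriform) cortex pyramidal neurons. Provides a synthetic
    dendritic morphology generator with SWC import/export, a branched-cable
    compartmental engine with Hodgkin-Huxley style somatic channels and
    voltage-dependent NMDA receptor conductances, stochastic vesicular
    release, presynaptic train generators mimicking mitral-cell firing, and
    the stimulation protocols used to study dendritic nonlinearities:
    input-output curves with logistic threshold detection, bias-input pairing
    on same/sister/different branches, clustered versus dispersed synaptic
    drive under in vivo-like background activity, and glomerular combination
    selectivity, together with the derived statistics (peak and area,
    background subtraction, pairing nonlinearity, threshold reduction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
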