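Package: gnpneuro
Title: Electrodiffusive Gauss-Nernst-Planck Modelling of Ion Channels and
    Neuronal Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-form electrodiffusive (Gauss-Nernst-Planck) membrane
    mathematics linking ionic permeability to conductance through the
    intramembrane concentration profile, characterization of single-channel
    rectification (GABAA, AMPA and leak channels, apparent and latent
    conductance/reversal pairs), a family of whole-neuron dynamical models
    with ion-concentration dynamics and Na+/K+-ATPase pump balance (cHH,
    fGNP, GNP, vGNP, kvGNP, navGNP, iHH), time integration with spike
    detection and firing-state classification, and fixed-point continuation
    with saddle-node and Hopf detection for depolarization-block stability
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
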