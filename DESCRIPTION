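Package: boolcell
Title: Multi-Scale Agent-Based Simulation of Cell Populations with
    Stochastic Boolean Signalling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates heterogeneous cell populations in which every cell
    agent carries a continuous-time stochastic Boolean signalling model
    whose inputs are read from a simulated microenvironment (diffusing
    substrates, contacts) and whose read-outs drive phenotype
    (proliferation, apoptosis, non-apoptotic death, secretion).  Combines
    an asynchronous Gillespie kernel on Boolean networks written in a
    MaBoSS-style text dialect, an off-lattice centre-based mechanical
    model of soft-sphere cells with differential adhesion, and a
    finite-volume reaction-diffusion solver for extracellular substrates.
    Ships a reconstructed TNF/NF-kB cell-fate decision network and
    scripted scenarios for monolayer dose-response, spheroid treatment
    regimes, heterogeneous tumour clones under oxygen competition, and
    differential-adhesion cell sorting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    png,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
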