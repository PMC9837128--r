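Package: mornet
Title: Stochastic and Deterministic Modelling of mu-Opioid Receptor Signalling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and parameter estimation for an 11-species, 11-reaction
    mass-action model of mu-opioid receptor (MOR) signalling: ligand binding,
    the G-protein cycle, and betagamma-mediated calcium-channel inhibition.
    Provides an exact Gillespie stochastic simulator of the underlying Markov
    jump process with ensemble statistics and batch-means confidence intervals,
    the deterministic reaction-rate-equation counterpart, a two-stage fitting
    procedure that estimates reaction rate constants from FRET time series of
    G-protein subunit dissociation, a seeded synthetic FRET data generator, and
    the scenario studies comparing the ligands fentanyl and NFEPP across pH
    levels and reactive-oxygen-species conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    nortest,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
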