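Package: beamlab
Title: Neutron Beam Filtration Dosimetry for Accelerator-Based BNCT
Version: 0.1.0
Authors@R:
    person("beamlab", "developers", email = "beamlab@example.org",
           role = c("aut", "cre"))
Description: Desk-scale evaluation pipeline for lithium-6 fluoride
    thermal-neutron filters in accelerator-based boron neutron capture
    therapy (BNCT). Provides a parametric epithermal source model, analog
    Monte Carlo neutron/photon transport with track-length fluence tallies
    through collimator/filter/phantom geometries, KERMA-based four-component
    dosimetry with RBE/CBE biological weighting, beam figures of merit
    (advantage depth, maximum treatment time, skin dose, off-axis flatness),
    gold-wire activation analysis with cadmium-difference thermal flux
    recovery, and voxel-phantom dose-volume-histogram evaluation with a
    synthetic head phantom generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
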