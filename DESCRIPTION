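Package: weldtherm
Title: Coupled Electro-Thermal Simulation and Analysis of High-Frequency
    Vessel Welding
Version: 1.0.0
Authors@R:
    person("Weldtherm", "Developers", email = "weldtherm@example.org",
           role = c("aut", "cre"))
Description: Tools to study tissue temperature during high-frequency
    electric welding (electrosurgical vessel sealing). Provides a voxel-grid
    coupled solver for the quasi-static electric potential and the Pennes
    bioheat equation with temperature-dependent tissue conductivities,
    drive calibration against temperature anchors, infrared thermography
    profile comparison (fitting degree, thermal diffusion width, isotherm
    deviation), a Raman amide-III pipeline (smoothing, polynomial baseline
    removal, pseudo-Voigt peak calibration, band ratios), T-peel strength
    normalization and group statistics, welding-phase classification, and
    synthetic-data generators for every analysis stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
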