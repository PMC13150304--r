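Package: hydrocap
Title: Soil-Plant Hydraulic Simulation with Plant Water Storage Capacitance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates water flow along the soil-plant-atmosphere continuum as
    a resistor-capacitor chain: Brooks-Corey soil retention and radial flow to
    a single root, a vulnerability-modified xylem pathway, and a linear
    pressure-volume plant water storage compartment. Transpiration is
    partitioned at every time step into root water uptake and storage
    discharge by iteratively solving for the xylem water potential. Two
    stomatal regulation strategies (a fixed leaf-water-potential threshold and
    a flexible rule maximizing transpiration per unit leaf water potential)
    limit transpiration. Includes the field-data pipelines that parameterize
    and test such models: whole-plant conductance and vulnerability
    calibration from leaf campaigns, capacitance estimation from root-segment
    drydowns, sap-flow versus root-water-uptake time-lag analysis, and
    synthetic-data generators with known ground truth for all three
    observation kinds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
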