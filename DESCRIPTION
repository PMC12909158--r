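Package: evlpsim
Title: Lumped-Parameter Simulation of Ventilation and Perfusion During Ex
    Vivo Lung Perfusion
Version: 0.1.0
Authors@R:
    person("Evlp", "Maintainer", email = "maintainer@evlpsim.org",
           role = c("aut", "cre"))
Description: Mechanistic simulation of donor lungs on an ex vivo lung
    perfusion (EVLP) circuit.  A lumped-parameter ordinary differential
    equation model couples a pressure-ramp mechanical ventilator, linear
    single-compartment lung mechanics, alveolar-capillary gas exchange with
    bicarbonate buffering of carbon dioxide, and an acellular perfusion
    circuit with intrapulmonary shunt and alveolar dead-space compartments.
    The package simulates left-atrial partial gas pressures at the
    ventilator-cycle level, generates synthetic EVLP monitor records
    (oxygenation challenges with realistic sensor noise), calibrates the
    intrinsic parameters (airway resistance, anatomical dead space, shunt
    and dead-space fractions) against such records, and provides Morris
    elementary-effects global sensitivity analysis and Monte-Carlo
    uncertainty quantification of the model outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
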