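Package: icpulse
Title: Coupled Stokes-Biot Simulation of Cardiac-Induced Intracranial
    Pulsatility
Version: 0.1.0
Authors@R:
    person("icpulse", "developers", email = "icpulse@example.org",
           role = c("aut", "cre"))
Description: Scenario-driven simulator of cardiac-induced intracranial
    pulsatility. The brain parenchyma is modelled as a linear poroelastic
    medium in a three-field (displacement, pore pressure, total pressure)
    Biot formulation, coupled to time-dependent Stokes flow of
    cerebrospinal fluid (CSF) in the subarachnoid space and ventricles
    through Beavers-Joseph-Saffman transmission conditions. The system is
    driven by a prescribed pulsatile net blood inflow acting as a uniform
    parenchymal volume source and closed by an exponential
    pressure-volume-index compliance condition at the spinal outlet.
    Includes an idealized tagged tetrahedral geometry generator, a
    monolithic implicit-Euler P2/P1 mixed finite-element solver, a lumped
    two-compartment compliance oracle, quantities-of-interest
    postprocessing (intracranial pressure probes, stroke volumes,
    transmantle gradients, displacement extrema, compliance partition) and
    a manufactured-solution verification harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
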