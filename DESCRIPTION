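Package: csfdyn
Title: Lumped-Parameter Craniospinal Cerebrospinal Fluid Dynamics
Version: 0.1.0
Authors@R:
    person("CSF Dynamics", "Maintainers", email = "maintainers@csfdyn.org",
           role = c("aut", "cre"))
Description: Tools for zero-dimensional modelling of craniospinal
    cerebrospinal fluid (CSF) dynamics. Preprocesses cardiac-gated
    phase-contrast MRI flow waveforms (monotone cubic interpolation, periodic
    moving-average smoothing, zero net flow), derives inlet boundary signals
    for the ventricular and basilar compartments, and couples them to
    resistive and two-element windkessel outlet models of CSF absorption and
    buffering. Includes compliance calibration against a target intracranial
    pulse pressure, a Gaussian cough-transient source with amplitude
    selection, Darcy porous-zone resistances emulating foramen magnum
    obstruction of graded severity (as in Chiari type 1 malformation), a
    two-compartment intracranial/spinal transient network solvable
    monolithically or through a perturbation-Jacobian outlet-coupling
    algorithm, post-processing metrics (pulse amplitudes, cranio-spinal
    pressure differences, longitudinal impedance, Reynolds number), and a
    synthetic waveform generator with known ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
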