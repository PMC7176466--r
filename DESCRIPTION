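Package: lungeit
Title: Regional Lung Mechanics Monitoring with Electrical Impedance Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A unified pipeline for thoracic electrical impedance tomography (EIT)
    during mechanical ventilation. Provides a 2-D finite-element forward model with
    adjacent current stimulation, one-step Gauss-Newton difference imaging with
    noise-figure-calibrated regularization and electrode-movement compensation,
    zero-phase respiratory-band filtering with automatic breath detection,
    functional-EIT lung region identification with automatic thresholding, and
    regional maps of dynamic respiratory-system compliance, overdistension and
    reversible atelectasis across a recruitment/PEEP-titration protocol. A phantom
    simulator generates voltage streams, ventilator logs and ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
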