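Package: gaitdyn
Title: Predictive Gait Dynamics from Leg Length, Body Mass and Walking Cadence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts sagittal-plane lower-limb gait dynamics over the full
    gait cycle from three scalar subject parameters: leg length, body mass and
    walking cadence. Joint angles come from a Fourier-series empirical model
    fitted by linear least squares; ground reaction forces from Newtonian
    models of a three-link single-support chain and a two-link double-support
    chain, with per-foot loads in double support obtained by a linear
    body-mass-transfer split; joint moments from Lagrangian inverse dynamics
    of the same point-mass chains. Includes evaluation metrics (RMSE, relative
    RMSE, Pearson correlation), a synthetic multi-trial pseudo-measurement
    generator for validation workflows, and CSV import/export of gait
    waveforms.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
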