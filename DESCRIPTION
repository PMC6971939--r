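Package: spiralflow
Title: Pseudo-Spiral Cartesian 4D Flow MRI Simulation, Compressed-Sensing
    Reconstruction and Wall Shear Stress Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing tiny-golden-angle pseudo-spiral Cartesian
    k-space sampling schedules for accelerated 4D flow cardiovascular MRI,
    simulating retrospectively gated four-point flow-encoded multi-coil
    acquisitions on a digital pulsatile vessel phantom, reconstructing the
    undersampled k-t data with a temporal total-variation compressed-sensing
    solver, and quantifying hemodynamics (time-resolved flow rate, stroke
    volume, wall shear stress) with Bland-Altman and orthogonal-regression
    comparison across acceleration factors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml,
    RNifti
Config/testthat/edition: 3
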