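Package: ectfield
Title: Adaptive-Conductivity Volume-Conductor Modeling of ECT Impedance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for representative-frequency (1 kHz) quasi-static modeling
    of electroconvulsive therapy (ECT) current flow and impedance. Includes
    Fourier analysis of alternating-polarity stimulus pulse trains, lumped
    R-RC equivalent-circuit fitting of low-current electrode-body impedance
    spectra, synthetic multilayer head phantoms with bifrontal pad
    electrodes, a finite-element Laplace solver in which superficial-scalp
    conductivity adapts piecewise-linearly to the local electric field, and
    subject-specific calibration of scalp conductivity parameters against
    clinical static (2 uA) and dynamic (900 mA) impedance pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    Matrix,
    minpack.lm,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
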