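Package: equigait
Title: Equine Training Activity Recognition from Leg Accelerometers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recognising horse jumping and dressage training
    activities from leg-worn tri-axial accelerometers. Provides a synthetic
    labeled-data generator with gait-specific beat structure, windowing and
    handcrafted signal features, a hybrid convolutional classifier that fuses
    raw windows with global features, a velocity regressor, autocorrelation
    stride-mechanics estimation, a hierarchical multi-phase dressage model
    with superclass modes, and quadratic discriminant pace classification on
    height and velocity with group velocity profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    ggplot2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
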