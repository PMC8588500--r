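Package: emgflow
Title: Two-Stage Hand-Gesture Recognition from Multichannel Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: A two-stage framework for recognizing hand gestures from
    multichannel surface electromyography (sEMG). Active segments are
    located and relabeled with a Teager-Kaiser energy detector, multivariate
    variational mode decomposition (MVMD) extracts narrow-band joint
    spatial-temporal oscillations, classical time-domain features route each
    window to a coarse gesture superclass, and a depthwise-separable
    convolutional network resolves the exact gesture within the superclass.
    Includes a synthetic multichannel sEMG generator, Ninapro-style MAT-file
    input, HDF5/CSV interchange, tenfold cross-validation, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    signal,
    e1071,
    MASS,
    class,
    randomForest,
    rpart,
    yaml,
    jsonlite,
    data.table,
    rhdf5
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
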