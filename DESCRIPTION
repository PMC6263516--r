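Package: iss2har
Title: Inertial Signal-to-Image Encoding and CNN Activity Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes windowed triaxial inertial sensor signals (accelerometer,
    gyroscope) into RGB images by splitting each min-max normalized value into
    its integer part and two two-digit decimal fields, one per color channel,
    so that the image representation is exactly invertible at four-decimal
    precision. Provides four baseline encoders for comparison (multichannel,
    raw signal plot, spectrogram, recurrence plot), a compact six-convolution
    CNN classifier (UCNet6) trained with SGD plus momentum, sliding-window
    segmentation and multi-device synchronization of raw recordings, a
    synthetic multi-subject recording generator with class-distinct
    quasi-periodic structure, confusion-matrix evaluation with
    leave-one-subject-out splits, and a command-line pipeline chaining
    simulation, encoding, training and evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    png,
    signal,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
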