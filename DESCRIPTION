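Package: rasterspike
Title: Rasterizing 1D Biosignals into Binary Images for CNN Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts one-dimensional non-stationary biosignals (extracellular
    neural spikes, EEG) into two-dimensional binary pixel images by quantizing
    sample amplitudes onto a pixel grid and joining consecutive samples with
    Bresenham's integer line algorithm, so that image-based deep learning
    models can classify signal shape. Includes a ground-truth spike-recording
    simulator (cosine-times-Gaussian action-potential templates, Poisson
    firing, additive Gaussian noise at configurable signal-to-noise ratios),
    an EEG-like seizure/non-seizure epoch generator, windowing and labeling
    utilities, a native implementation of a modified LeNet-5-style 2D
    convolutional network trained with RMSprop, confusion-matrix metrics, and
    an end-to-end reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
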