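Package: mirtissue
Title: Label-Free Tissue Classification for Mid-Infrared Hyperspectral Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Pipeline for label-free classification of colorectal tissue in
    quantum-cascade-laser infrared hyperspectral images: ENVI cube I/O,
    signal-to-noise and amide I quality control, resonant-Mie scatter
    correction by extended multiplicative signal correction (EMSC) with a
    van de Hulst extinction basis, Savitzky-Golay second-derivative
    spectroscopy, curation of two-level spectral databases by unsupervised
    clustering, a cascaded two-level random-forest pixel classifier with
    Gini variable importance, index-color rendering of tissue label maps,
    and sample-level tumor diagnosis with a 2 percent tumor-pixel threshold.
    Includes a synthetic tissue-phantom generator with known ground truth
    for validation of the full workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    ranger,
    png
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
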