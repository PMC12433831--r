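Package: xirplesion
Title: Quantification of Xirp-Positive Sarcomeric Lesions in Muscle
    Immunofluorescence Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Semi-automatic detection and quantification of xirp 1/2-positive
    sarcomeric lesions in single-channel immunofluorescence images of skeletal
    muscle cross-sections. Provides a trainable multiscale pixel classifier,
    connected-component lesion morphometry with physical-unit calibration and
    micro/macrolesion size filters, a seven-parameter per-section readout, a
    normality- and variance-guided group-comparison decision tree with
    interobserver concordance analysis, and a synthetic tissue and cohort
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    nnet,
    nortest,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
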