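Package: ctiq
Title: Quantitative CT Image Quality Metrics with a Synthetic Phantom Testbed
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for task-generic quantitative CT image-quality assessment on
    homogeneous and low-contrast phantom inserts: region-of-interest noise,
    contrast-to-noise ratio, noise texture deviation (the fraction of pixels
    deviating more than three standard deviations from the ROI mean),
    homogeneity, radially averaged noise power spectra with their average
    spatial frequency, the circular-edge task-based transfer function with its
    half-maximum frequency, and dose-reduction estimation from log-log
    noise-dose regression with delta-method confidence intervals. A synthetic
    phantom-image generator renders a semi-anthropomorphic upper-abdomen
    phantom and synthesizes colored Gaussian noise with prescribed radial
    spectra, dose and slice-thickness scaling, and optional blotch artifacts,
    so every stage of the pipeline is verifiable without scanner data. Image
    stacks round-trip through a raw-array + JSON sidecar fixture format or a
    minimal DICOM series reader/writer.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
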