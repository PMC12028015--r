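Package: laminacount
Title: Region-Wise Neuron Counting and Survival Analysis in Spinal Cord Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying neuronal survival in two-channel
    (neuronal marker + nuclear marker) histological cross-sections of the
    injured mouse spinal cord. Provides a synthetic-section generator with
    known ground truth, threshold- and probability-map-based neuron
    detection, matching and consensus of point annotations from multiple
    observers (agreement classes and a weighted reference count),
    Bland-Altman repeatability and reproducibility statistics, thin-plate-
    spline landmark registration of sections to a Rexed-laminae atlas, and
    region-wise survival quantification with nonparametric group
    comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    xml2
Suggests:
    mgcv,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
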