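Package: spheroscreen
Title: Spheroid Morphometry, Plate Quality Control and Dose-Response
    Analysis for 3D Cytotoxicity Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for high-throughput cytotoxicity screening of single
    spheroids cultured in ultra-low-attachment 96-well plates. Provides
    automated morphometry of phase-contrast spheroid images (Yen entropy
    thresholding, artifact cleaning, hole filling, debris separation, area
    and Feret diameters, equivalent-sphere volume), assay-quality
    statistics for plate validation (Z-factor and Z', signal window,
    coefficient of variation, robust outlier removal, D'Agostino-Pearson
    normality, t-test detection power), four-parameter logistic and
    biphasic dose-response fitting with three IC50 combination procedures
    (pooled, geometric mean, shared-logIC50 extra-sum-of-squares F-test),
    and ground-truthed synthetic image and plate generators for end-to-end
    validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    graphics,
    grDevices,
    minpack.lm,
    EBImage,
    png,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
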