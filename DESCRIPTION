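Package: msimodal
Title: Multimodal Mass Spectrometry Imaging Correlation Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for correlating lipid and elemental mass spectrometry
    imaging of the same tissue section. Reads centroided MALDI-type imaging
    data from imzML, renders per-lipid ion images with a ppm mass window,
    total-ion-current normalisation and quantile hotspot clipping, and
    annotates peaks by accurate mass against a lipid mass list. Converts
    time-resolved LA-ICP-MS line scans to rasters and quantifies them
    against spiked gelatine external calibration standards. Co-registers
    the two modalities from landmark correspondences with a least-squares
    affine fit, and compares registered channel stacks pixel-to-pixel by
    Pearson correlation, with heatmap and two-colour composite output.
    Includes a phantom generator with analytic ground-truth correlations
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    xml2,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
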