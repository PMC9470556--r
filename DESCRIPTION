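Package: jmoct
Title: Multi-Contrast Jones-Matrix OCT Analysis for Zebrafish Xenograft Imaging
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for polarization-sensitive
    Jones-matrix optical coherence tomography (JM-OCT) of the zebrafish
    tail musculature and xenograft tumor models. Provides a speckle
    phantom generator with known ground truth, computation of the four
    JM-OCT contrast channels (scattering intensity, local birefringence
    with a reliability map, degree of polarization uniformity, and
    complex-correlation angiography), rule-based segmentation of the
    upper musculature, longitudinal per-animal quantification including
    a birefringence abnormality statistic and exact Mann-Whitney rank
    sum tests, Kaplan-Meier survival curves with an observed-over-
    expected hazard ratio and log-rank test, and en-face vessel metrics
    (mean vessel length, vessel density).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), methods
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
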