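Package: canimpact
Title: Agreement Between 3D and 2D Severity Indexes for Impacted Maxillary Canines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Landmark-based scoring of impacted maxillary canines with the
    three-dimensional KPG severity index (six 0-5 subscores on the mesiodistal,
    vertical and bucco-palatal axes of cusp tip and root apex) and with three
    panoramic-radiograph measures (Stewart's cusp-to-occlusal-plane distance,
    Ericson-Kurol sectors, and the alpha inclination angle), together with the
    agreement and diagnostic-accuracy statistics used to compare them: Cohen's
    kappa, Kendall's W with tie correction, the phi coefficient, chi-square
    tests with and without Yates continuity correction, sensitivity,
    specificity, predictive values, likelihood ratios, and a Bloch-Kraemer
    kappa sample-size calculation. A synthetic-data module simulates 3D canine
    displacement over an arch template, a distorted panoramic projection, and
    noisy multi-rater multi-timepoint rating panels, so the full pipeline is
    testable without radiographic images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
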