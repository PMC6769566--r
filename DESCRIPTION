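Package: msiTriage
Title: MALDI Mass Spectrometry Imaging Triage of Thyroid Cytology Specimens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pixel-resolved MALDI-TOF mass spectrometry imaging (MSI) analysis
    of thyroid fine needle aspiration (FNA) cytology. Provides imzML input and
    output, per-spectrum preprocessing (median baseline subtraction, moving
    average smoothing, total ion current normalization, signal-to-noise peak
    picking, ppm-tolerance peak alignment), region-of-interest (ROI) feature
    construction with intra- and inter-patient prevalence filters, a
    cross-validated Lasso-penalized logistic model of malignancy, and
    specimen scoring in three modes (per-ROI, whole-average, pixel-by-pixel)
    with quartile-based benign/malignant triage calls and probability maps.
    A synthetic cohort generator with known ground truth emulates FNA
    cytospin MSI datasets, including paucicellular, heterogeneous-mixture and
    colloid-rich challenge specimens, so the full pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    png,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
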