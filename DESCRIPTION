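Package: cirrhotex
Title: Texture-Based Quantification of Liver Cirrhosis from T2-Weighted MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies liver cirrhosis from a single T2-weighted MR slice by
    dynamic gray-level scaling of the 12-bit intensity range to 64 levels,
    ROI-restricted Otsu thresholding to suppress hepatic vessels, and
    first-order texture features (mean, standard deviation, Shannon entropy)
    of the retained parenchyma. Includes the full diagnostic-evaluation layer
    (ROC curves with Youden operating points, AUC with Hanley-McNeil
    significance, Cohen's kappa, pooled and Welch t-tests, 95% confidence
    intervals) and a seeded synthetic phantom generator so the pipeline can
    be exercised and validated without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
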