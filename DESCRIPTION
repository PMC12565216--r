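Package: steatoscan
Title: Computer-Aided High-Frequency Ultrasound Assessment of Murine Hepatic Steatosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative assessment of hepatic steatosis in mouse
    models from high-frequency B-mode ultrasound. Implements a reproducible
    computer-aided texture pipeline (circular region-of-interest extraction,
    Gaussian speckle smoothing, mean +/- 3 SD intensity correction, relative
    256-level discretization, gray-level co-occurrence matrix features), the
    hepatorenal index, semiquantitative conventional-ultrasound (CUS) and
    histological steatosis severity (SSS) score models, diagnostic-screening
    statistics with data-derived cutoffs, tie-corrected Spearman correlation
    with Bonferroni control, a fully-developed-speckle B-mode simulator whose
    echogenicity ratio and texture heterogeneity track steatosis grade, and a
    45-animal cohort generator matching published joint score distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
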