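Package: petsegtex
Title: Segmentation-Dependent Reproducibility and Prognostic Screening of PET Texture Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compare tumour-segmentation algorithms for quantitative
    18F-FDG PET radiomics. Simulates SUV-scaled PET phantoms with heterogeneous
    focal lesions, partial-volume blur and noise, together with imperfect
    multi-reader freehand contours and feature-driven survival outcomes.
    Implements three delineation approaches (freehand ingestion, 40%-of-maximum
    thresholding, and a three-class spatially regularized Bayesian mixture
    segmenter), a frozen 83-feature texture panel (first-order, grey-level
    co-occurrence, run-length, size-zone and neighbourhood grey-tone difference
    matrices, and fractal measures) on 64-level quantized volumes of interest,
    inter-observer agreement statistics (Jaccard overlap, intraclass
    correlation with bootstrap comparison of algorithms), and a univariate Cox
    proportional-hazards screen with AIC bootstrap intervals. All results are
    returned as tibbles with broom-style tidiers and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
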