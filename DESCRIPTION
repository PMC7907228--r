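Package: sqm
Title: Slice-Wise Sharpness Metrics and Quality Scoring for Spheroid Z-Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: No-reference sharpness assessment of fluorescence z-stacks of 3D
    multicellular spheroids, for ranking optical clearing protocols. Implements
    seven slice-wise focus measures (intensity variance, gradient-magnitude
    variance, Laplacian variance, histogram threshold, histogram entropy,
    Fourier high-pass frequency threshold, and bivariate periodogram kurtosis),
    stack-maximum intensity normalization, Otsu foreground masking, a
    moment-centroid internal-circle mask, a single-value 0-1 score per stack
    region with rescaling to a 1-5 expert scale, Pearson correlation against
    expert scores, and Kruskal-Wallis group comparison with Dunn's post-hoc
    test. A synthetic spheroid phantom generator with a tunable clearing-quality
    parameter makes the whole pipeline testable without microscope data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    EBImage,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
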