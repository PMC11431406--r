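Package: qthresh
Title: Self-Adaptive Tsallis Entropy Multi-Level Image Thresholding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Histogram-based multi-level image thresholding driven by
    non-extensive (Tsallis) entropy. The non-extensive parameter q is
    estimated per image by maximising the q-redundancy of the gray-level
    histogram, and m thresholds are selected by maximising the
    pseudo-additive Tsallis objective, with maximum-Shannon-entropy (Kapur)
    and fixed-q Tsallis baselines. Includes exhaustive and differential
    evolution optimisers, PSNR/SSIM segmentation quality metrics, seeded
    synthetic multimodal image and fixed-background scene-series
    generators, batch evaluation, and most-suitable-rate summaries.
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
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
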