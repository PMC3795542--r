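Package: rmpenhance
Title: Rotational Morphological Contrast Enhancement for Greyscale Biomedical Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Contrast enhancement of low-contrast greyscale biomedical images
    (mammograms, chest radiographs and similar modalities) by rotational
    morphological processing (RMP). Provides flat greyscale morphology
    (dilation, erosion, opening, closing) with disc, square and line
    structuring elements, rotation-combined (isotropic) opening and closing,
    white and black top-hat transforms, and the full top-hat contrast
    enhancement operator in which each top-hat image is histogram-equalized
    and linearly stretched before recombination with the original image.
    Also includes the contrast improvement ratio (CIR) quality metric, two
    reference enhancement baselines (multiscale retinex and contrast-limited
    adaptive histogram equalization), a synthetic low-contrast phantom
    generator for end-to-end evaluation, and lossless greyscale image I/O
    (PNG, TIFF, PGM).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    png,
    tiff,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
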