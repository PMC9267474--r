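Package: msipath
Title: Multispectral Microscopy Analysis of H&E Skin Sections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calibrates raw narrow-band microscope frames of stained skin
    sections to reflectance (dark-frame subtraction, blank-slide referencing,
    frame averaging, adaptive two-dimensional gamma illumination correction),
    segments nuclei, keratin pearls and collagen from band-specific images by
    contrast-limited local histogram equalization, median filtering and
    adaptive mean thresholding, quantifies the nucleocytoplasmic ratio in
    sliding 100x100-pixel windows, and separates normal skin from cutaneous
    squamous cell carcinoma with Student's t-tests and ROC/AUC analysis.
    Ships a ground-truthed synthetic multispectral scene generator so the
    whole pipeline is testable end to end without slide data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    png,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
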