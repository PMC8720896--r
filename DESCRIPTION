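Package: huespectra
Title: Hue Spectra Fingerprinting for Produce Color Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Saturation-weighted hue histograms ("hue spectra") summarize the
    color of a whole image of fruit or vegetables while implicitly suppressing
    neutral (white/gray/black) backgrounds, because neutral pixels carry zero
    chroma and never pass the saturation threshold. The package computes hue
    spectra from 24-bit RGB images, characterizes spectral peaks, compresses
    spectra to the gravity point of their polar figure (Polar Qualification
    System), and fits chemometric regressions (PLS1 on spectra, ordinary
    multivariate regression on RGB summary statistics) predicting produce
    quality parameters such as soluble solids content or firmness. A
    deterministic synthetic-scene generator provides ground-truth fixtures
    and a command-line interface supports batch processing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, tools, jsonlite, withr, png, jpeg, tiff
Suggests: testthat (>= 3.0.0), mixOmics, knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
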