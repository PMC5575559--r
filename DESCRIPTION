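Package: carrierscope
Title: Non-Invasive Image Analysis of Adherent Cell Growth on Microcarriers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of epi-illumination microscopy images of
    adherent cells (e.g. mesenchymal stem cells) growing on spherical
    microcarriers in stirred suspension culture. Provides adaptive confluence
    segmentation from local intensity variability, circular-Hough microcarrier
    detection and isolation, Laplacian-of-Gaussian cell detection with
    hemisphere-corrected per-carrier counts, microcarrier aggregate flagging,
    culture-level growth statistics, and a ground-truthed synthetic scene
    renderer for validating every stage without a microscope. Includes a
    command-line interface for batch processing of image stacks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    yaml,
    png,
    tiff,
    stats,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
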