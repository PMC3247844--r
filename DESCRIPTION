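Package: cyanovia
Title: Autofluorescence-Based Viability Assay for Unicellular Cyanobacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-analysis pipeline for scoring viability of unicellular
    cyanobacteria (e.g. Synechocystis) from two-channel autofluorescence
    micrographs taken in a calibrated counting chamber. Viable cells emit red
    chlorophyll autofluorescence while non-viable cells show an unspecific
    green autofluorescence; the pipeline segments both channels with Kapur
    maximum-entropy thresholding, registers connected components as particles,
    removes sub-area artefacts, classifies each particle by its mean green
    intensity, and converts pooled counts to cells per millilitre. Also
    provides fluorescent colony counting on agar-plate images normalised to an
    all-viable control, the methanol-extract chlorophyll concentration
    formula, and a seeded synthetic micrograph generator with exact ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    optparse,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
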