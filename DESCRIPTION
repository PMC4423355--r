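Package: blastoquant
Title: Quantification of Spatial Gene Expression from Blastoderm Embryo Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An image-processing pipeline for building quantitative
    spatio-temporal gene expression atlases from colorimetric in-situ
    hybridisation images of early fly (blastoderm) embryos. From four-channel
    embryo micrographs (bright-field stain, DIC morphology, nuclear
    counterstain, membrane detail) it segments and aligns embryos, extracts
    averaged RGB expression profiles along a midline strip spanning 10% of
    embryo height, unmixes NBT/BCIP (purple) and FastRed (red) stain
    intensities, fits expression-domain boundaries with clamped cubic splines,
    stages embryos by nuclear density into cleavage cycles and time classes,
    and integrates boundary positions across embryos into per-gene,
    per-time-class summary tables (mean, median, SD, MAD in percent embryo
    length). A synthetic embryo-image generator with ground-truth manifests
    makes every pipeline stage testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
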