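Package: ramanxome
Title: Single-Cell Raman Map Segmentation, Activation Classification, and
    Cross-Modal Transcriptome Linkage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Label-free analysis of hyperspectral Raman maps of single B
    cells. Segments maps into nucleus, cytoplasm and background by pooled
    ("common") k-means clustering of pixel spectra, applies a
    Savitzky-Golay based three-step background subtraction, discriminates
    non-activated (D0) from cytokine-activated (D4) cells via a
    nucleic-acid peak ratio, principal component analysis and Fisher
    linear discriminant analysis with leave-one-out validation, and links
    the Raman phenotype to bulk transcriptomes through a partial least
    squares (PLS2) regression that predicts Raman principal-component
    scores from transcript read counts and ranks transcripts by Variable
    Importance in Projection. A synthetic-data module generates Raman
    cohorts and matched count matrices with full ground truth so that
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    MASS,
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
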