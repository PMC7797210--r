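Package: ttquant
Title: Quantification of T-Tubule Organization and L-Type Calcium
    Channel Activity in Cardiomyocytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Image, topography and electrophysiology analysis for studies of
    cardiomyocyte membrane architecture. Quantifies striated membrane staining
    by density and Fourier power of regularity, detects and classifies
    T-tubule openings in scanning ion conductance microscopy height maps,
    idealizes single L-type calcium channel recordings to estimate channel
    counts, open probability and per-area channel density (including pipette
    tip geometry from pipette resistance), measures proximity ligation assay
    staining density, and reproduces the associated statistical comparisons
    from raw observations or printed summary statistics. A synthetic-data
    generator emulates every input modality with known ground truth so the
    full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
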