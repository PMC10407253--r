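Package: temsig
Title: Quantification of Endothelial Signaling During Neutrophil
    Transendothelial Migration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image- and trace-based quantification of endothelial signaling
    during leukocyte transendothelial migration (TEM). Implements kinase
    translocation reporter (KTR) analysis from two-channel time-lapse
    microscopy (rolling-ball background subtraction, nuclear and cytoplasmic
    ring segmentation, overlap tracking, cytoplasm/nucleus ratio extraction),
    baseline normalization and Ward.D2/Manhattan responder clustering of
    single-cell activity traces, Laplacian-of-Gaussian spot detection for
    apical filopodia density with junctional exclusion, monolayer
    morphometry, two-wave adhesion spatial statistics against a random-dot
    null, FRET and FRAP ratiometric normalizations and fluorophore crosstalk
    matrices. Ground-truth-annotated synthetic data generators (movies,
    traces, point sets, spot fields) make every stage testable without raw
    microscopy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    yaml,
    jsonlite
Config/testthat/edition: 3
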