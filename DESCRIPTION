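Package: msacquisim
Title: Simulation and Benchmarking of LC-MS/MS Acquisition Strategies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: A desk-scale digital twin of an untargeted-metabolomics LC-MS/MS
    instrument. Synthetic chemical mixtures with known ground truth are
    acquired by interchangeable controllers implementing data-dependent
    (Top-N with dynamic exclusion) and data-independent (SWATH, All-Ion
    Fragmentation) strategies; DIA runs are deconvoluted by extracted-ion-
    chromatogram correlation; annotation performance is benchmarked against
    the known true fragmentation spectra with binned cosine similarity.
    Simulated runs are exportable as standard indexed mzML, and externally
    produced mzML and feature tables can enter the deconvolution and
    evaluation stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    Matrix,
    mzR,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
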