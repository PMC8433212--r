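Package: nucleogradient
Title: Spatial Gradient Analysis of Pre-Ribosomes in Nucleolar Tomograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of the radial organization of ribosome
    biogenesis inside intact nucleoli imaged by cryo-electron tomography.
    Provides robust sphere fitting of pre-ribosome positions with iterated
    outlier rejection, mass-calibrated density segmentation and radial mass
    spectra, bias-mitigated template matching with truncated dual references
    and proximity consensus, replicated simulated-annealing multireference
    classification with quorum consensus, Fisher-Pitman permutation tests of
    radial distributions, and a ground-truthed synthetic tomogram generator
    for validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
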