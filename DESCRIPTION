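Package: mplexpheno
Title: Multiplex Immunofluorescence Simulation, Unmixing and Cell Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale digital-pathology pipeline for tyramide-signal-amplification
    (Opal) multiplex immunofluorescence panels. Generates ground-truthed synthetic
    tissue scenes (lymphoid hot spots, nonspecific co-staining, segmentation
    spillover, thickness-scaled autofluorescence, per-channel exposures), builds
    fluorophore spectral libraries and unmixes multichannel images by per-pixel
    non-negative least squares with autofluorescence subtraction, detects nuclei on
    the DAPI plane with watershed splitting and expands them to membrane
    compartments, classifies cells by threshold-based sequential binary hierarchical
    phenotyping with configurable detection orders and expected/unexpected
    decision-tree classes, and validates panels with Spearman rank correlation,
    Bland-Altman limits of agreement, Mann-Whitney U, paired t and a 10-percentage-
    point positivity criterion.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    randomForest,
    stats,
    tiff,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
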