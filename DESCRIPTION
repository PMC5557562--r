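Package: metharg
Title: Arginine Methylation Site Prediction from Protein Sequence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Window-based prediction of protein arginine methylation sites.
    Builds arginine-centered peptide datasets from annotated FASTA input with
    identity-based redundancy reduction, encodes physicochemical and
    positional-frequency features, ranks them by information gain with MDL
    discretization, trains a radial-basis-function support vector classifier
    with cross-validated grid search, and evaluates models with sensitivity,
    specificity, accuracy, Matthews correlation and ROC analysis. A synthetic
    motif-planting sequence generator makes the full pipeline testable without
    any external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    Biostrings,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
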