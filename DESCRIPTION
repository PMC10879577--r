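Package: travelnet
Title: Traveling-Model (Cyclical Weight Transfer) Training for Multi-Center 3D Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and evaluates the traveling-model (cyclical weight transfer)
    paradigm for distributed training of 3D convolutional disease classifiers across
    many heterogeneous medical centers, together with its centralized baseline.
    Provides a synthetic multi-center cohort generator with a long-tailed center-size
    profile, per-center train/test splitting with demographic balancing for small
    centers, a seeded 3D phantom renderer with scanner and center nuisance effects,
    a compact fully convolutional 3D network with Adam optimisation implemented via
    'RcppArmadillo', reproducible travel schedules with fixed or per-cycle random
    center orderings, AUROC evaluation, and a cycle-stability summary.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
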