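Package: segpeaks
Title: Supervised Changepoint Segmentation for ChIP-Seq Peak Calling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Peak detection in ChIP-seq coverage profiles by exact penalized
    maximum-likelihood changepoint segmentation. Implements functional
    dynamic-programming solvers for the unconstrained and the Up-Down
    (background/peak) constrained models under Poisson, negative binomial and
    Anscombe-transformed Gaussian noise; post-processing rules (thinnest,
    largest, max jump) that turn unconstrained segmentations into peaks;
    penalty-space exploration (sequential search, CROPS, CROCS) that
    enumerates all optimal models between two peak-count bounds; supervised
    learning of the penalty and negative-binomial dispersion parameters from
    labeled regions (constant and linear penalty methods, squared-hinge
    interval regression); over-dispersion diagnostics and the normalized
    information distance for replicate robustness; a synthetic-profile
    generator; and a command-line interface over bedGraph/BED files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
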