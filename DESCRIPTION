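Package: vusbench
Title: Circularity-Free Benchmarking of Missense Pathogenicity Predictors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating in silico missense-variant pathogenicity
    predictors against multifactorial-likelihood classifications without
    training/evaluation circularity. Implements the posterior-probability
    model of the multifactorial likelihood framework and its inversion to
    prior-independent likelihood-ratio thresholds, curation of classified
    and prior-independent evaluation variant sets, harmonization of
    Align-GVGD, SIFT, MutationTaster2 and PolyPhen-2 outputs to binary
    calls, confusion-matrix performance statistics (sensitivity,
    specificity, accuracy, Matthews correlation coefficient) with
    family-weighted clinical impact counts, m-of-n ensemble voting with
    exact Poisson-binomial expected performance under independence, and a
    seeded Gaussian-copula generator of synthetic variant tables with
    correlated tool errors.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
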