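Package: BayesPAGE
Title: Global Hierarchical Bayesian Classification of Differentially
    Expressed Proteins in 2D PAGE Experiments
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Case-control analysis of spot intensities from two-dimensional
    polyacrylamide gel electrophoresis (2D PAGE). Missing spot values are
    modelled as arising either from non-expression or from expression below
    the limit of detection, via a left-censored truncated-normal mixture
    likelihood per spot. A global hierarchical layer shrinks per-spot means,
    case-control intensity differences (asymmetric Laplace law) and
    logit-scale expression propensities towards shared distributions, with
    all parameters recovered by adaptive block-updating random-walk
    Metropolis-Hastings with parameter expansion. Spots are classified as
    differentially expressed when the 95% highest posterior density interval
    of the intensity difference and/or the expression-propensity difference
    excludes zero. A per-spot maximum-likelihood fit of the same censored
    mixture with a 2-df likelihood ratio test is included as the univariate
    baseline, together with simulation generators with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Proteomics, Bayesian, DifferentialExpression, GeneExpression
RoxygenNote: 7.3.3
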