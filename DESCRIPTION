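Package: bardms
Title: Barcode-Resolved Deep Mutational Scanning with Negative Binomial
    Mixed Models
Version: 0.1.0
Authors@R:
    person("Jordan", "Mercer", email = "jmercer@example.org",
           role = c("aut", "cre"))
Description: Analysis framework for barcode-resolved deep mutational
    scanning (DMS) of cell-surface receptors. Builds and filters
    variant-barcode maps from tagged sequencing reads, assembles per-sample
    barcode count tables with stop-codon-derived depth offsets, and fits a
    per-position mixed-effects negative binomial model (Laplace-integrated
    barcode random intercepts) to estimate per-variant, per-condition
    effects with Wald/Benjamini-Hochberg inference. Downstream analytics
    include marginal-mean defect/rescue contrasts for corrector treatment
    response, PCA-based signaling-bias scores across conditions, and a
    Bayesian errors-in-variables meta-regression for ligand-specific
    effects. A generative simulator with known ground truth supports
    end-to-end testing without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
SystemRequirements: C++17
Config/testthat/edition: 3
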