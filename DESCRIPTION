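Package: netfilter
Title: Mode-of-Action Identification by Gene Network Filtering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies directly perturbed genes (compound mode of action)
    from steady-state expression compendia by gene network filtering. For
    each gene a short list of candidate regulators is selected by
    equal-frequency discretization, information-gain ranking and
    correlation-based forward subset search; an epsilon support-vector
    regression model is fitted on the training samples; bootstrap residual
    distributions yield one-sided normal p-values for the treated sample,
    and genes inconsistent with the trained regulatory model are reported.
    Includes a steady-state Hill-kinetics network simulator with lognormal
    noise and SNR-controlled single-gene perturbations for benchmarking,
    and hypergeometric term enrichment with conditional testing on a term
    hierarchy.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    igraph,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    pROC,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
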