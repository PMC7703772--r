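Package: baycount
Title: Bayesian Recovery and Normalization of Single-Cell RNA-Seq Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Recovers, imputes and normalizes single-cell RNA-seq count
    matrices under a binomial model of mRNA capture combined with
    empirically estimated gene-specific negative-binomial priors. The
    posterior of the original transcript count of each gene in each cell
    is a shifted negative binomial available in closed form; point
    estimates (posterior mean or MAP) or posterior samples (3D array) are
    returned. Includes per-cell capture-efficiency estimation calibrated
    to a mean capture efficiency, global or per-group ("local")
    empirical-Bayes prior estimation with dispersion shrinkage, a
    generative simulator of binomially thinned negative-binomial counts,
    and evaluation statistics (dropout rates, CV, Gini coefficient,
    median-of-adjusted-p differential expression aggregation) for
    validating count recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
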