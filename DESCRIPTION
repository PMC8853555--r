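Package: admixkit
Title: Allele-Frequency Based Admixture Inference with f-Statistics and
    Admixture Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimation of f2, f3 and f4 statistics from diploid SNP
    genotypes with sample-size bias corrections and weighted block-jackknife
    standard errors; rank-based tests for the number of ancestry streams and
    admixture-proportion estimation with plausibility classification
    (qpWave/qpAdm style); admixture-graph representation, expected
    f-statistics, covariance-weighted graph fitting with non-negative branch
    lengths, and an exhaustive search that maps a target population onto
    every edge (or pair/triple of edges) of a skeleton graph with
    log-likelihood and worst-residual model-selection rules. Includes
    readers/writers for EIGENSTRAT and PLINK binary genotype formats and a
    Wright-Fisher style allele-frequency drift simulator with closed-form
    expected statistics for end-to-end validation on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
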