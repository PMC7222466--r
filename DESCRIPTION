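Package: constclock
Title: Constant-Distance Proposal Kernels for Relaxed-Clock Phylogenetic MCMC
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A self-contained Bayesian relaxed-clock phylogenetic MCMC
    sampler built around proposal kernels that move divergence times and
    branch rates jointly while holding the implied genetic distances
    constant: a constant-distance move on internal nodes and three root
    strategies (simple distance, small pulley, big pulley), each with its
    Metropolis-Hastings-Green ratio. Includes an HKY85 pruning likelihood,
    log-normal relaxed-clock and coalescent/Yule priors, a clock
    standard-deviation operator with rate quantile matching, quadrature
    oracles for validating the kernels by sampling from the prior on
    three-taxon fixtures, dating on a fixed unrooted tree via midpoint
    rooting, and a scaled well-calibrated simulation study.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    pracma,
    stats,
    utils
Suggests:
    Matrix,
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
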