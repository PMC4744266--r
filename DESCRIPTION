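Package: multinetSBM
Title: Multiple-Network Stochastic Block Models via Variational Bayes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Hierarchical Bayesian stochastic block models for module
    identification across several noisy observations of the same network.
    A latent root partition is linked to per-network instantaneous
    partitions through transition matrices, and a closed-form mean-field
    variational Bayes algorithm infers all posteriors. Includes the
    single-network baseline as the degenerate one-network limit, held-out
    edge prediction with ROC/PR evaluation, a planted-partition generator
    with degree-preserving Maslov-Sneppen rewiring for benchmarking, and
    the standard clustering and protein-complex evaluation metrics (NMI,
    overlap score, Frac, Sn/PPV/Acc, Sep).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite, yaml, optparse
Suggests: testthat (>= 3.0.0), pROC, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
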