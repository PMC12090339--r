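Package: aldesim
Title: Active-Learning Directed Evolution Campaigns with FRET-Based
    Fitness Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for machine-learning-guided protease engineering by
    batch Bayesian optimization. Designs random combinatorial variant
    libraries over a small set of mutable residues, converts two-channel
    FRET plate-reader kinetics into wild-type-normalized fitness scores
    (ratio computation, truncation at a ratio threshold, initial-rate
    slope fitting), fits an ensemble of bootstrapped neural-network
    regressors over one-hot encoded sequences as an approximate Bayesian
    posterior, proposes new variant batches by Thompson sampling, and
    orchestrates reproducible multi-round create-test-learn campaigns.
    A synthetic-data module generates ground-truth epistatic fitness
    landscapes and simulated fluorescence plates so the full pipeline is
    testable in silico.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    nnet,
    stats,
    tibble,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
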