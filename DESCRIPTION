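Package: mdeq
Title: Bayesian Ordering Questions for Multi-Condition Tag-Count Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scores genes in tag-count expression libraries (SAGE, MPSS,
    RNA-seq style enumeration data) by the posterior probability that a
    user-formulated multi-condition ordering question (for example
    "A < B < C") is true. Per-library mRNA abundances get Beta(N+1, T-N+1)
    posteriors under a uniform prior; replicate libraries form equal-weight
    beta mixtures; question probabilities are estimated by joint Monte
    Carlo over the posterior draws. Includes probability-cutoff gene
    ranking, randomization-null gene-set enrichment on the
    probability-weighted gene list with optional fuzzy annotation weights,
    a binomial-sampling simulator with planted monotone profiles, and a
    ROC harness for power studies.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
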