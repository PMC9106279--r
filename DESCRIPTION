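Package: notepol
Title: Sentiment, Polarity, and Topic Analysis of Clinical Nursing Notes
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for mining free-text electronic nursing
    clinical notes: lexicon-based sentiment scoring against emotion,
    integer-valence and binary dictionaries; a valence-shifter sentence
    polarity score built from context clusters of negators, amplifiers
    and deamplifiers; monthly sentiment series compared across patient
    groups with dynamic time warping; latent Dirichlet allocation by
    collapsed Gibbs sampling with model selection by semantic coherence
    and exclusivity and post hoc covariate prevalence inference; and
    classifier-based group discrimination with a full evaluation suite
    (AUC, sensitivity, specificity, Cohen's kappa, accuracy against the
    no-information rate). A synthetic-corpus generator with known ground
    truth (planted topics, sentiment mixes, valence shifters, copy-paste
    duplicates, shift and month metadata) supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
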