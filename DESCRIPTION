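Package: arttrans
Title: Multi-State Models of Male Alternative Reproductive Tactics in Social Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying male alternative reproductive tactics (mate
    guarding, sneaking, reproductive inactivity) in cooperatively breeding
    social groups followed through repeated oestrus events. Provides the data
    derivation rules that turn daily focal observations, weight records,
    demography, pedigree relatedness and litter records into per-oestrus
    tactics and covariates; a Bayesian multi-state model of between-oestrus
    tactic transitions with an absorbing dead state, multinomial-logit
    transition probabilities and crossed random effects; hierarchical outcome
    models for oestrus weight loss, siring success and male mate choice; and a
    synthetic-population generator with known true parameters so the whole
    pipeline can be validated by simulation-based parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    coda,
    jsonlite,
    rjags,
    stats,
    utils
Suggests:
    nnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
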