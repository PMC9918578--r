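Package: lexnetgrow
Title: Semantic Network Growth Models of Early Word Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying how toddler vocabularies grow through
    structured semantic environments. Builds directed semantic networks
    from multi-response word-association norms and from windowed word
    co-occurrence in child-directed speech, estimates per-word age of
    acquisition from CDI-style production norms, computes growth values
    under three network growth models (preferential attachment,
    preferential acquisition, lure of the associates), and compares
    models of lexical acquisition with a softmax likelihood, nested
    likelihood-ratio tests, BIC, and false-discovery-rate control.
    Includes representational similarity analysis with a split-half
    permutation null, small-world indices with lattice and random
    reference graphs, taxonomic distance ratios with BCa bootstrap
    intervals, repeated-measures ANOVA with Greenhouse-Geisser
    correction, and a fully synthetic data generator with known ground
    truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    boot,
    dplyr,
    igraph,
    jsonlite,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
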