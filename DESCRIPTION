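Package: liquidassoc
Title: Genome-Wide Liquid Association Screening for Dynamic Co-Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for liquid association (LA) analysis of gene expression:
    score how the co-expression of a gene pair (X, Y) changes with the level of
    a third "scouting" gene Z, assess significance against permutation null
    distributions of extreme LA scores, designate scouting genes with a binned
    modified liquid association (MLA) estimator based on Stein's lemma, screen
    genome-wide for high-scoring triplets, select scouting leaders, and extend
    the score to gene-trait pairs with a quantitative phenotype in the Y role.
    Includes a synthetic-data generator that plants triplets with a known
    conditioner-dependent correlation for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
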