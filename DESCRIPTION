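Package: segrec
Title: Multi-Gene Tree Reconciliation with Segmental Duplications and Losses
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconciles a forest of rooted binary gene trees with a rooted
    binary species tree under a duplication-loss model in which co-mapped
    duplications are charged as segmental events: the duplication cost is
    delta times the sum, over species-tree nodes, of the height of the
    forest of duplications mapped there, plus lambda times the loss count.
    Provides the LCA-mapping solution (optimal when delta <= lambda), an
    exact fixed-parameter branch-and-bound solver for delta > lambda, a
    brute-force enumeration oracle for validation, and a seeded simulator
    of gene families evolving inside a species tree with planted segmental
    duplication episodes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
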