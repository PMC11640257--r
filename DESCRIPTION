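Package: mipsa
Title: Two-Stage Gene Selection with Mutual Information and Binary Particle Swarm Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Selects compact, discriminative gene subsets from labeled
    gene-expression matrices using a two-stage filter/wrapper strategy: a
    mutual-information filter ranks genes by their dependence on a binary
    class label (in bits, via equal-frequency discretization), keeps the
    top-k and removes highly correlated redundant genes; a binary particle
    swarm optimizer then searches subsets of the filtered pool, minimizing
    a fitness that combines cross-validated support-vector-machine error
    with relative subset size. Includes leave-one-out evaluation with
    confusion-matrix metrics, ROC/PR curves, a seeded synthetic-data
    generator with planted informative genes for end-to-end validation,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    pROC,
    withr
Config/testthat/edition: 3
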