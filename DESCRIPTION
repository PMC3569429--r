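Package: potentialnet
Title: Potential-Theory Link Prediction for Directed Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing link formation in directed networks under the
    potential-theory hypothesis: every directed arc drops exactly one unit of
    an integer node potential, and local structures whose nodes admit such
    potentials are favoured. The package tests potential-definability of a
    digraph, enumerates the six minimal loop-embedded subgraphs of orders 3
    and 4 under a generalized (non-induced) subgraph definition, derives the
    twelve subgraph-completion link predictors obtained by removing one arc
    from each pattern, and evaluates them with the AUC protocol on random
    train/probe splits. Seeded generators for sparse directed networks,
    layered DAGs and planted Bi-fan benchmarks make the whole pipeline
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    Matrix,
    purrr,
    rlang,
    tibble,
    tidyr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
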