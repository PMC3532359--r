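Package: threeprop
Title: Adaptive Label Propagation on Networks via Weighted Short Random Walks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Semi-supervised node-label prediction on undirected weighted
    networks. Implements the 3Prop scorer, which ranks nodes by a weighted
    sum of length-1, -2 and -3 random-walk probabilities into positively
    labelled nodes, with the three weights fitted by linear discriminant
    analysis, alongside the generic label-propagation (GLP) framework it
    generalizes (symmetric and asymmetric graph normalizations, truncated
    power-series and exact linear-system solutions, and their exact
    correspondence). Includes AUROC and average-precision evaluation with
    nested cross-validation, seeded generators for assortative,
    disassortative and shared-neighbour synthetic labelling regimes, and
    random-walk mixing diagnostics (stationary distribution and total
    variation convergence curves).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
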