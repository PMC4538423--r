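Package: bmkc
Title: Module-Level Differential Coexpression Analysis via Biweight
    Midcorrelation and k-Clique Percolation
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects overlapping gene modules whose coexpression changes
    between two conditions (e.g. normal and disease). Pairwise gene
    similarity is measured with the outlier-robust biweight
    midcorrelation; condition-specific correlation matrices are
    binarized with differential-coexpression threshold rules (gain,
    loss, or absolute-difference of correlation); overlapping modules
    are extracted by the clique percolation method (k-clique
    communities); and module significance is assessed by a group-wise
    permutation test on a global differential-coexpression score. A
    seeded synthetic benchmark generator with a planted coexpressed
    block supports power studies and recovery evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: GeneExpression, Network, GraphAndNetwork, DifferentialExpression
RoxygenNote: 7.3.3
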