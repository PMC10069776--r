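Package: traitimpute
Title: Real-Data-Driven Selection of Imputation Methods for Mixed-Type
    Species Trait Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation-based selection of an imputation method for
    species-by-trait tables containing continuous, count, binary and
    multi-categorical traits. Missingness is simulated in a near
    complete-case table under MCAR, MAR and MNAR mechanisms; candidate
    imputers (mean/mode, k-nearest neighbour with Gower distances,
    iterative random forests, and chained equations with predictive mean
    matching) are run with and without phylogenetic eigenvectors derived
    from a principal coordinates analysis of patristic distances; mean
    squared error and proportion-falsely-classified rates over replicates
    feed a majority vote that picks the best-suited method, which is then
    applied to the original incomplete table. Includes phylogenetic signal
    estimators (Pagel's lambda, Fritz and Purvis' D) and a synthetic
    generator of trees and correlated mixed-type traits with tunable
    phylogenetic signal.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    yaml,
    ape,
    nnet,
    randomForest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phytools
Config/testthat/edition: 3
RoxygenNote: 7.3.3
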