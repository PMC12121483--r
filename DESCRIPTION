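Package: appclust
Title: Automated Projection Pursuit Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Recursive divisive clustering of high-dimensional numeric data by
    automated projection pursuit: each step scans all orthogonal 2D projections,
    finds minimum-density decision boundaries as extremal paths through a
    Gaussian-smoothed histogram augmented with a parabolic "gravity" potential,
    ranks candidate boundaries by the Calinski-Harabasz index, and splits along
    the best one until no admissible split remains. Includes a supervised-UMAP
    label-transfer pipeline for benchmarking cluster assignments against ground
    truth (cluster alignment by maximum-overlap matching, misclassification and
    F1 reports), evaluation metrics, synthetic mixture generators, and
    command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    uwot,
    clue,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
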