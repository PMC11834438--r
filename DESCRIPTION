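Package: codetect
Title: Probability-Based Co-Detection Networks for Microbiome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds microbial co-existence networks from genus-by-sample
    abundance tables using a probability-based co-detection model (PBCDM):
    genus pairs are flagged when their observed co-detection deviates from
    the independence expectation by more than k standard deviations of the
    pairwise deviation distribution. Includes comparator network builders
    (centered log-ratio Pearson, Spearman, and a SparCC implementation with
    bootstrap pseudo p-values), graph centralization scores (closeness,
    betweenness, eigenvector), a percolation-style network-shearing
    algorithm that extracts a core network, a subsampling workflow that
    locates the minimum sample size at which network attributes stabilise,
    and synthetic-data generators for presence/absence tables with planted
    pairwise dependencies and compositional counts from a correlated
    log-normal basis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
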