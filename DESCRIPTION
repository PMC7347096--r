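Package: budzones
Title: Hidden Semi-Markov Segmentation of Axillary Bud-Fate Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models one-year-old fruit-tree shoots as bivariate categorical
    sequences of axillary bud fates (latent, vegetative, floral) and associated
    flower-bud counts indexed by node rank, and segments them into successive
    homogeneous zones (basal, median, distal) with a left-right hidden
    semi-Markov chain ending in an absorbing end state. Provides exact
    forward likelihood computation, expectation-maximization estimation with
    explicit state-occupancy distributions, semi-Markov Viterbi restoration of
    the optimal segmentation, contextual zone statistics, nonparametric group
    comparisons (Kruskal-Wallis, Wilcoxon-Mann-Whitney, Pearson chi-squared,
    Spearman correlations with significance limits, compact letter displays),
    and a synthetic shoot-sequence generator with parameter-recovery
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    withr,
    jsonlite,
    generics,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
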