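Package: mkse
Title: Multiscale Partition-Based Kolmogorov-Sinai Entropy for Heartbeat Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the partition-based Kolmogorov-Sinai entropy of
    RR-interval (heart rate variability) time series across time scales.
    Series are coarse-grained over scale factors, symbolized against uniform
    amplitude partitions, and their per-symbol algorithmic information content
    is approximated with a lossless pair-coding dictionary compressor in the
    CASToRe family; the resulting multiscale entropy surfaces are compared
    between subject groups with Mann-Whitney and Kruskal-Wallis grids under
    Bonferroni correction. Includes synthetic symbolic sources with known
    entropy rate and AR(1) surrogate RR cohorts for validation, plain-text RR
    readers, a reproducible pipeline runner, and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
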