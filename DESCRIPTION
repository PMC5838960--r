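Package: mixqc
Title: Measurement Assurance for Genome-Scale miRNA Profiling with
    Reciprocal Reference Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality-control dashboard for genome-scale microRNA profiling
    built around a reciprocal reference-mixture design: three pure total-RNA
    components (liver, brain, placenta) and two mixtures of them with swapped
    proportions (1:1:2 and 1:2:1). Predicted mixture signals are computed from
    the pure profiles under a linear mixing model, and the package derives the
    dashboard of performance metrics from the comparison of observed and
    predicted log2 ratios: tissue-selectivity classification, bias (median
    deviation) and precision (IQR), the reliable region of the dynamic range,
    designed-truth ROC curves and AUC, and constrained least-squares
    deconvolution of the mixture proportions with bootstrap confidence
    ellipses. A synthetic-data generator with known ground truth supports
    testing of every metric, and ggplot2 panel builders render the full
    dashboard view.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    patchwork,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
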