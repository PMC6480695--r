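Package: icibench
Title: Validation and Combination of Immune Checkpoint Inhibitor Response Biomarkers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for benchmarking transcriptomic and genomic
    biomarkers of response to immune checkpoint inhibitors (ICI). Ships a
    built-in 18-marker panel (single genes, gene-set signatures, tumour
    mutational load and plug-in algorithmic scores), scores each marker per
    patient from TPM expression matrices and somatic mutation lists, assigns
    responder labels from heterogeneous clinical annotations, evaluates every
    marker on every cohort by empirical ROC curves with Youden-index
    dichotomization, then combines uncorrelated markers two ways: an
    exhaustive majority-voting search over all marker subsets, and a binomial
    logistic model validated by repeated 80/20 holdout. A synthetic cohort
    generator with a latent binormal marker model makes the whole pipeline
    runnable and testable without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
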