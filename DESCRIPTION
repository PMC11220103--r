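Package: multipletr
Title: Compound Poisson Multiplet Detection for Single-Cell Multiomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects doublets and triplets in droplet-based single-cell data
    using a compound Poisson mixture model over stable features. Each modality
    (RNA, ADT, or ATAC gene activity) is fitted with a truncated-Poisson prior
    on the number of cells per droplet and Gamma or Gaussian per-cell
    contribution distributions with a shared decline effect; per-droplet
    posterior probabilities of containing 1, 2, or 3 cells are combined across
    modalities with goodness-of-fit and consistency based softmax weights, so
    droplets are classified as singlet or multiplet without a user-chosen
    threshold. Includes generative and artificial-multiplet simulators and
    precision/recall/F1/AUPRC evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
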