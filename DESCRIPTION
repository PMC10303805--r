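Package: msiflnp
Title: Microbe-Disease Association Prediction by Denoised Similarity
    Fusion and Label Propagation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts unobserved microbe-disease associations from a sparse
    binary association matrix. Three association-derived similarity kernels
    per entity type (cosine, Gaussian interaction-profile, and
    linear-neighborhood reconstruction weights) are fused by a non-linear
    cross-iteration scheme, denoised by truncated singular value
    decomposition, and known associations are diffused over the resulting
    microbe and disease networks by closed-form linear-neighborhood label
    propagation in both directions. Includes a planted-block synthetic
    data generator, repeated k-fold cross-validation with AUC scoring,
    parameter-grid sweeps, broom-style tidiers, ggplot2 diagnostics, and a
    small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    quadprog,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
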