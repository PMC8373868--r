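Package: invasim
Title: Agent-Based Simulation of Tumor-Immune-EMT Dynamics and Invasion-Free Survival
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid stochastic/deterministic multiscale model of carcinoma
    progression. Tumor cells are discrete agents carrying pathway mutations
    (proliferation, apoptosis, immune evasion) and a continuous
    epithelial-mesenchymal transition (EMT) score; natural killer cells,
    cytotoxic T lymphocytes, regulatory T cells and TGF-beta are continuous
    variables coupled to the agents under a cycling inflammation scheme.
    The package simulates in-silico patient cohorts, computes invasion-free
    survival (Kaplan-Meier curves, restricted mean survival time, log-rank
    tests) and performs Morris elementary-effects global sensitivity
    analysis over parameter priors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    readr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    deSolve,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
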