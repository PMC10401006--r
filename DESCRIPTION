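Package: netwisdom
Title: Simulation and Analysis of Networked Collective Intelligence
    Experiments in Clinical Risk Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing multi-round, networked
    belief-revision experiments in which groups of clinicians estimate a
    patient's risk (0-100) and choose a treatment recommendation over three
    rounds, either embedded in a degree-regular information-sharing network
    (each participant sees the mean estimate of their network neighbours
    before revising) or revising independently. Provides a synthetic-cohort
    generator with DeGroot-style revision dynamics and an accuracy-dependent
    self-weight, the experiment's outcome measures (absolute error, min-max
    normalized accuracy, trial-level aggregation, quartile and decile
    binning, revision magnitude, recommendation correctness and switching),
    nonparametric inference with small-sample exact and permutation modes
    (Wilcoxon rank-sum and signed-rank, Jonckheere-Terpstra trend test,
    Spearman rank correlation, Hodges-Lehmann shift intervals, simulated
    power for the rank-sum design), and a seeded simulate/analyze/report
    pipeline over plain-text data files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
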