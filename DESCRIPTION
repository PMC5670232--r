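Package: recallshift
Title: Baseline-Shift Analysis of Intracranial ECoG During Categorized Free Recall
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing high-frequency broadband (HFB, 60-160 Hz)
    amplitude in intracranial ECoG recordings during categorized free recall:
    line-noise removal, common-average re-referencing and artifact masking;
    Hilbert-based HFB envelope extraction with rest-period normalization;
    identification of visually responsive and category-selective electrodes
    (including the category-selectivity index); quantification of sustained
    category-specific baseline shifts during recall and their discrimination
    from transient burst dynamics via percentile-gain profiling of simulated
    burst and shift models; event-locked recall, intrusion and prompt analyses
    with cluster-based permutation statistics; and multitaper spectral
    estimation of raw-LFP and ultra-slow HFB fluctuations. A seeded synthetic
    ECoG generator emulates the task structure and signal statistics so that
    every stage is testable by parameter recovery without patient data.
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
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pbkrtest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
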