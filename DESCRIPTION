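Package: rickertnr
Title: Ricker-Model Assessment of Trap-Neuter-Return Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing trap-neuter-return (TNR) programs for
    free-roaming cats with the discrete-time Ricker population model.
    Computes annual per-capita growth rates from surgery-index or census
    counts, fits density-dependence regressions with studentized-residual
    outlier exclusion and LOWESS smoothing, derives the Malthusian
    multiplier, carrying capacities and critical neutering rates, runs
    deterministic Ricker simulations with dynamical-regime classification,
    aggregates per-cat surgery records into monthly pregnancy-proportion
    trends, and emits a four-criteria assessment report. A synthetic-data
    module generates Ricker-governed and managed-decline program datasets
    for parameter-recovery and model-mismatch studies.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
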