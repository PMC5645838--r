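Package: markovcea
Title: Markov Cohort Cost-Effectiveness Modelling for Oncology Treatment Strategies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Decision-analytic cost-effectiveness modelling with discrete-time
    Markov cohort models: occupancy traces with explicit accrual and discounting
    conventions, micro-costing aggregation into per-cycle state costs,
    incremental cost-effectiveness ratios with dominance handling, one-way
    (tornado) sensitivity analysis, Monte Carlo probabilistic sensitivity
    analysis with cost-effectiveness plane and acceptability-curve summaries,
    and generators of synthetic but valid model specifications for property
    testing. Ships the base-case parameter set of a published four-state
    metastatic colorectal cancer model (XELOX versus XELOX plus bevacizumab
    from a Brazilian public-hospital perspective) as a worked fixture.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, ggplot2, jsonlite, optparse
Config/testthat/edition: 3
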