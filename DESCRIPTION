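Package: diabprev
Title: Lifetime Cost-Effectiveness of Lifestyle Intervention for Diabetes
    Prevention
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Annual-cycle cohort state-transition model of progression from
    prediabetes to type 2 diabetes and its complications in a Chinese
    healthcare setting: Weibull time-to-diabetes onset fitted to long-term
    trial survival curves, life-table mortality with disease multipliers,
    discounted quality-adjusted life-year and cost accrual, incremental
    cost-effectiveness with dominance classification, deterministic
    calibration to published control-arm outcomes, and one-way plus
    probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    yaml,
    jsonlite,
    survival,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
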