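Package: cvpload
Title: Time-Weighted Central Venous Pressure Exposure Analysis in Sepsis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes trapezoidal central venous pressure (CVP) exposure
    metrics on irregularly sampled ICU time series: CVP load, elevated-CVP
    (ECVP, > 10 mmHg) load and duration, and their time-normalized forms.
    Provides cohort selection with the standard 24 h start / 72 h monitoring
    windows, a statistical battery linking normalized ECVP load to 28-day
    mortality (Kaplan-Meier with log-rank, lowess dose-response, median-split
    and quartile subgroup comparisons, univariate screening with forward
    stepwise logistic regression), and a seeded synthetic ICU cohort
    generator with Ornstein-Uhlenbeck CVP dynamics for fully reproducible,
    access-free pipeline runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    survival,
    nortest,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
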