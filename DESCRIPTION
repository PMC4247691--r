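Package: rtimort
Title: Winter Excess and Trends in RTI-Related Child Mortality from Linked Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the contribution of respiratory tract
    infections (RTIs) to child mortality from death certificates linked to
    hospital episode records. Implements time-windowed ICD-10 code-cluster
    phenotyping (30-day pre-death episode window for RTI evidence, 1-year
    lookback for chronic conditions), annual Poisson trend models with
    AIC-based change-point selection, winter/summer person-time-adjusted
    mortality rates with excess winter deaths estimated by rate differencing,
    and chronic-condition comorbidity reporting. Ships a seeded synthetic
    linked-record generator emulating the statistical structure of national
    death-registration and hospital-admission data, so the full pipeline is
    testable without access to restricted microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
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
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
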