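Package: ineqtrend
Title: Linear Trends in Health Inequalities and the Likelihood of Eradication
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for presenting and interpreting linear trends in health
    inequalities across socioeconomic groups. Scores socioeconomic status as a
    within-population fractional rank of ordinal parental education, estimates
    outcome prevalence at both extremes of the socioeconomic scale per survey
    wave from cluster random-intercept logistic regression, propagates
    coefficient uncertainty by Monte-Carlo simulation, fits the linear
    relationship between low- and high-status prevalence across waves with
    ellipse-derived 95 percent confidence regions, and quantifies the
    likelihood of eradication: the chance that, were the linear trend to
    continue, prevalence falls below a target (default 5 percent) in both
    groups at once. Includes a synthetic micro-data generator with known
    ground truth for validation, end-to-end pipeline drivers, and plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    lme4,
    MASS,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
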