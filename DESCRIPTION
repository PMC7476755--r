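Package: tojkit
Title: Analysis of Spatial Temporal-Order-Judgment Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing two-alternative spatial temporal-order-judgment
    (TOJ) data: trial filtering and response recoding, probit-line estimation of
    the point of subjective simultaneity (PSS) and just noticeable difference
    (JND), permutation t-tests and one-way ANOVA, binomial random-intercept
    mixed models with likelihood-ratio and Wald contrast tests, r-equivalent
    effect sizes, and maximum-likelihood estimation of the stimulus onset
    asynchrony at which reaction times peak. Includes a synthetic-observer
    generator (cumulative-Gaussian observers with lapses, between-participant
    variability, and reaction times peaking near the PSS) so that every stage
    of the pipeline can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    withr
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
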