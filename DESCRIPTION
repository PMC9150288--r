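Package: pregprofile
Title: Preconception Pregnancy-Outcome Risk Profiles via Nested Multistate Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and validates individualized preconception risk profiles for
    the joint outcome of a pregnancy attempt: no clinically-recognized pregnancy
    within a fixed window of menstrual cycles, clinical pregnancy loss, preterm
    birth, or full-term birth. A discrete-time (person-period logistic) hazard
    model for time to conception is composed with a multinomial logit model for
    the result of a recognized pregnancy, giving a four-category risk profile per
    individual. Two-stage outcome missingness is handled by sequential multiple
    imputation or inverse-probability weighting under a sequential
    missing-at-random assumption, and discrimination is assessed with the
    Hypervolume Under the Manifold (HUM) statistic, including a
    verification-bias-adjusted estimator and bootstrap optimism correction. A
    synthetic cohort simulator with known truth supports testing end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
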