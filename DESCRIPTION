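Package: mirvcea
Title: Markov Cohort Cost-Utility Modelling of Mirvetuximab Soravtansine
    in Platinum-Resistant Ovarian Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A cohort Markov state-transition pipeline for the health-economic
    evaluation of mirvetuximab soravtansine against standard chemotherapy in
    platinum-resistant ovarian cancer, from the perspective of German statutory
    health insurance. Fits exponential, Weibull, Gompertz, log-logistic and
    log-normal survival models to digitized Kaplan-Meier coordinates and selects
    an extrapolation by SSR/AIC/BIC; converts progression-free and overall
    survival curves plus background mortality into per-cycle transition
    probabilities for a three-state (stable, progressive, dead) model; runs the
    discounted cohort simulation accruing costs, life-years and QALYs; and
    computes incremental cost-effectiveness and cost-utility ratios,
    deterministic (tornado, bivariate-utility, threshold-price) and
    probabilistic (gamma/beta/lognormal Monte Carlo, CEAC) sensitivity
    analyses. Ships a synthetic-data generator emulating two-arm trial
    Kaplan-Meier curves and a background-mortality life table so the whole
    pipeline runs without access to trial data.
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
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
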