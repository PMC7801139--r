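Package: worklife
Title: Multistate Working Life Expectancy from Register Episode Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for estimating working life expectancy (WLE) and working
    years lost (WYL) between ages 50 and 63 from episode-level register data.
    Overlapping employment and benefit spells are resolved into one gap-free
    daily labor-market state trajectory per person over seven states (work,
    time-restricted work disability, unemployment, economic inactivity,
    disability retirement, retirement, death) with 27 allowed transitions.
    Transition-specific Cox proportional hazards models on an age time axis
    with delayed entry feed Breslow baseline cumulative hazards, an
    Aalen-Johansen product-integral estimator of transition probabilities,
    and expected-length-of-stay integration, with percentile bootstrap
    confidence intervals. Includes a job-exposure-matrix module for physical
    workload covariates and a synthetic register-data generator
    (continuous-time Markov chain with piecewise-constant, covariate-modified
    intensities) so the whole pipeline is testable without confidential data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr
Config/testthat/edition: 3
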