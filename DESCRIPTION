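Package: svyjoinpoint
Title: Joinpoint Trend Models for Individual-Level Complex Survey Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fits survey-weighted joinpoint (segmented) regression models to
    individual-level records from stratified multistage cluster samples.
    Provides log-normal models for positive continuous outcomes and logistic
    models for binary outcomes, a grid search over candidate joinpoint
    locations, a modified design-based AIC (m.dAIC) that uses an average
    design effect from Taylor-linearization sandwich covariances to choose
    the number of joinpoints, and annual percent change (APC/AAPC) trend
    summaries with design-correct degrees of freedom. Also includes the
    aggregate-level comparator (yearly weighted estimates with a full
    cross-year covariance capturing PSU overlap, GLS joinpoint fits and
    weighted-BIC selection) and a finite-population simulation engine for
    repeated cross-sectional cluster sampling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), optparse, jsonlite, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
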