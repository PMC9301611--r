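Package: scorecomp
Title: Individual-Level Comparability of General Intelligence Composites
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying whether two general intelligence composites
    (unit-weighted subtest sums normed to the IQ metric) are exchangeable for
    an individual test taker. Implements classical-test-theory reliability
    algebra (Cronbach's alpha, composite reliability from component
    reliabilities and covariances, disattenuation), true-score confidence
    intervals built from the standard error of estimate under four
    reliability regimes, six interval-overlap comparability criteria with IQ-
    and age-group breakdowns, differential external-validity comparison of
    standardized regression slopes with a 50 percent CI-overlap rule, and
    gamma generalized linear models with log link and two-SD-standardized
    predictors for intraindividual IQ differences. A one-general-factor
    synthetic cohort generator emulates standardization samples so the whole
    pipeline is testable without proprietary norm data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
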