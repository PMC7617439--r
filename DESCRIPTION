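Package: lifegap
Title: Life Expectancy and Years-of-Life-Lost in Matched Primary-Care Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating life expectancy and years-of-life-lost for a
    diagnosed-exposure group versus matched comparators in primary-care-style
    electronic health records. Implements exposure-density (incidence-density)
    1:10 matching with immortal-time-safe entry dates, Lexis splitting of
    follow-up into single-year-of-age person-time strata, Poisson smoothing of
    age-specific mortality rates (linear and quadratic age terms with a log
    person-time offset), period life tables in the Office for National
    Statistics style, and parametric-bootstrap confidence intervals obtained by
    simulating coefficient draws from the fitted model. A seeded synthetic
    cohort generator with Gompertz mortality and a configurable exposure
    rate-ratio stands in for licensed databases so the full pipeline is
    testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
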