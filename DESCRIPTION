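Package: effcov
Title: Variance Estimation and Confidence Intervals for Effective Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Point estimation and uncertainty quantification for effective
    coverage of health services, defined as the product of a service-coverage
    proportion (from an individual-level sample) and a facility-readiness
    measure (from an independent facility sample), at stratum, region, and
    national levels. Implements three confidence-interval methods: the exact
    (Goodman) variance of a product of independent proportions with Wald-type
    intervals, a logit-scale delta-method interval back-transformed to the
    probability scale, and a parametric percentile bootstrap. Includes a
    Monte-Carlo simulation engine for estimating the coverage probability of
    each interval method over grids of true proportions and sample sizes,
    with the degenerate-, invalid-, and undefined-interval accounting needed
    to compare methods near the 0/1 boundary, plus a synthetic stratum-table
    generator for end-to-end parameter-recovery checks.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
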