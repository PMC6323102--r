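Package: wildna
Title: Wild Bootstrap Inference for Multivariate Nelson-Aalen Estimators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Nonparametric inference for cumulative transition hazards in
    multistate event-history models satisfying Aalen's multiplicative
    intensity structure, with independent right-censoring and
    left-truncation.  Implements the Nelson-Aalen estimator with Aalen- and
    Greenwood-type variance estimators, wild-bootstrap resampling with
    white-noise multipliers (one independent multiplier per observed event
    increment), time-simultaneous equal-precision and Hall-Wellner
    confidence bands calibrated either by transformed Brownian bridges or by
    the wild bootstrap, linear bands, confidence bands for within-sample
    hazard differences, simultaneous confidence intervals and Sidak
    regions, Kolmogorov-Smirnov equality tests, equivalence tests by band
    inclusion, a two-sample test for proportional hazards with
    Kolmogorov-Smirnov and Cramer-von-Mises statistics, and simulation
    harnesses for empirical size and coverage studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), survival, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
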