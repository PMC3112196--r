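Package: eligsim
Title: Adjusting Cohort Mortality Predictions for Disease-Status
    Eligibility Criteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for adjusting model-based predictions of
    disease-specific mortality in volunteer cohorts for the component of
    the healthy-volunteer effect caused by disease-status enrollment
    criteria.  The adjustment models the interval between clinical
    diagnosis and death as an exponential distribution whose mean is
    estimated from stage-stratified Kaplan-Meier survival curves
    re-weighted to an external (registry) stage distribution, and embeds
    that interval in an individual-level rejection-sampling simulator of
    lung-cancer deaths driven by a two-stage clonal expansion (TSCE)
    survival model with smoking-history-dependent parameters.  Includes
    an exact quadrature oracle for the accepted-outcome distribution of
    the rejection loop, synthetic-cohort and synthetic-survival-record
    generators, and a replicate-trial engine with percentile confidence
    bands.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    deSolve,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
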