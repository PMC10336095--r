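Package: mrwell
Title: One-Sample Mendelian Randomisation for Well-Being Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for one-sample Mendelian randomisation of body mass
    index against ordinal subjective well-being outcomes across stratified
    biobank cohorts. Builds weighted and standardised genetic risk scores
    with block jack-knife weight estimation so that no individual's
    phenotype informs their own instrument, fits observational and
    two-stage least-squares causal models with proper instrumental-variable
    standard errors, pools stratum estimates by fixed-effects meta-analysis
    with I-squared heterogeneity, compares cohorts with the Fisher z
    method, screens for non-linearity with quadratic and fractional
    polynomial models selected by AIC, and estimates non-linear causal
    effects with a control-function instrumental-variable method.
    Includes a synthetic cohort generator with known ground truth
    (instrument, exposure, shared unobserved confounder, ordinal outcome)
    for calibration and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
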