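Package: resistinMR
Title: One-Sample Mendelian Randomization of Serum Resistin and
    All-Cause Mortality in Type 2 Diabetes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genetic instrumental-variable (one-sample Mendelian
    randomization) analysis of whether serum resistin causally affects
    all-cause mortality in type 2 diabetes. Provides genotype quality
    control (Hardy-Weinberg testing, missingness policy), genotype
    risk-score construction with category pooling, exposure-stage linear
    models with AIC coding selection and delta-method percent-change
    estimates, Cox survival models with robust variance, fixed-effect
    pooling and Cochran Q heterogeneity testing, a simulation-based
    supremum test of log-linearity based on cumulative martingale
    residuals, Wald-ratio and two-stage causal hazard-ratio estimators,
    Schoenfeld-type power calculations, and a multi-cohort synthetic
    data generator emulating the three-cohort study structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    jsonlite,
    withr
Config/testthat/edition: 3
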