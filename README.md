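# resistinMR

One-sample Mendelian randomization of serum resistin and all-cause
mortality in type 2 diabetes.

## What this package is for

Serum resistin is firmly *associated* with all-cause mortality in type 2
diabetes, but association may reflect confounding by inflammation,
adiposity or treatment. resistinMR implements the genetic
instrumental-variable analysis that asks whether the association is
causal, for a three-cohort prospective design: a genotype risk score
(GRS) — the per-subject count of resistin-increasing alleles of
rs3931020 and rs13144478 (0–4, with 3 and 4 pooled) — instruments
standardized log-resistin in Cox models of death.

The analysis layers are:

* **Genotype QC and instrument construction** — Hardy–Weinberg
  chi-square tests, complete-case missingness policy, GRS construction
  with category pooling, confounder-balance checks
  (`hwe_test`, `build_grs`, `confounder_balance`).
* **Exposure stage** — OLS of standardized log-resistin
  (`ln(resistin)` divided by its SD) on the GRS, categorical vs
  continuous coding selected by AIC, per-category percent changes of the
  reference mean with delta-method SEs
  (`fit_exposure_model`, `compare_codings`, `percent_change_means`).
* **Survival stage** — Cox Models 1–3 (increasing adjustment) per cohort
  and combined, fixed-effect pooling, Cochran Q heterogeneity with a
  robust-CI rule at p < 0.10, incidence rates, and a Kolmogorov-type
  supremum test of log-linearity based on cumulative martingale
  residuals with simulated residual patterns
  (`fit_cox`, `model_suite`, `pool_fixed_effect`, `heterogeneity_q`,
  `supremum_linearity_test`).
* **Causal stage** — the Wald ratio `b/a` (instrument–outcome over
  instrument–exposure effect) with delta-method variance
  `var(b)/a² + b²·var(a)/a⁴`, two-stage predictor substitution into a
  Cox model, and a Cochran Q comparison of causal vs observational
  log-HRs (`wald_ratio`, `two_stage_cox`, `causal_vs_observed_q`).
* **Power** — the Schoenfeld relation
  `D = (z₁₋α/₂ + z_power)² / (β² σ²ₓ)` and its inverses, plus
  simulation-based verification (`schoenfeld_events`, `detectable_hr`,
  `detectable_slope`, `simulate_power`).
* **Synthetic cohorts** — a generator whose defaults emulate the
  motivating study's structure (1,479 subjects in cohorts of
  350/698/431, ~403 deaths over ~12,454 person-years, published
  covariate and resistin marginals) with the causal structure
  SNPs → resistin → death plus shared confounders
  (`sim_config`, `simulate_multi_cohort`).

The methods vignette (`vignettes/resistin-mortality-mr.Rmd`) documents
the model, the generator's assumptions and every numerical choice.

## A worked example

```r
library(resistinMR)

cfg <- sim_config(seed = 1)            # defaults = the study conditions
d <- simulate_multi_cohort(cfg)        # 1,479 subjects, three cohorts
report <- run_all(d, seed = 1, n_sim_supremum = 2000)
report
#> Resistin-mortality Mendelian randomization report
#>   subjects: 1479; events: 380; person-years: 12593
#>   Model 1 combined HR per SD: 1.31 (1.19-1.45)
#>   Model 2 combined HR per SD: 1.26 (1.14-1.39)
#>   Model 3 combined HR per SD: 1.26 (1.14-1.39)
#>   causal HR per SD (two-stage): 0.87 (0.51-1.51); Q p = 0.199
```

The unadjusted Model 1 (1.31) exceeds the fully adjusted Model 3 (1.26)
because the generator's confounders raise both resistin and the hazard;
the true simulated causal HR is 1.27 per SD and sits inside the
two-stage CI. The supremum test on the same run does not reject
log-linearity (p = 0.95).

The published-summary replication surface needs no subject-level data
and no randomness:

```r
rs <- replicate_from_summaries()
round(rs$pooled_model1$hr, 2)                 # 1.39  (CI 1.27-1.53)
signif(rs$heterogeneity$p, 2)                 # 0.45
signif(rs$causal_vs_observed$p, 2)            # 0.074
round(rs$power$detectable_hr_per_sd, 2)       # 1.15
round(rs$power$detectable_hr_per_allele, 2)   # 1.19
```

These are the published combined Model-1 hazard ratio per SD of
log-resistin (inverse-variance pooling of the three cohort estimates),
the between-study heterogeneity p, the Cochran Q p-value comparing the
causal HR 2.17 (1.22–3.87) with the observational 1.27 (1.14–1.41), and
the detectable hazard ratios at 80% power with 403 events.

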