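#' Default per-cohort specification table
#'
#' Returns the built-in three-cohort specification (labels GHS, GMS, FMS)
#' used by [sim_config()]. Each row carries the cohort size, covariate
#' means/SDs or prevalences, the target raw-scale resistin mean and SD
#' (ng/ml), the target all-cause death incidence rate (events per 100
#' person-years), and the target mean follow-up with the half-width of the
#' uniform administrative-censoring jitter (years).
#'
#' The defaults emulate three Italian type 2 diabetes cohorts totalling
#' 1,479 subjects with 403 deaths over 12,454 person-years; incidence-rate
#' targets are 4.1, 2.7 and 3.9 per 100 person-years.
#'
#' @return A data.frame with one row per cohort.
#' @export
default_cohort_specs <- function() {
  data.frame(
    label          = c("GHS", "GMS", "FMS"),
    n              = c(350L, 698L, 431L),
    male_frac      = c(238 / 350, 344 / 698, 224 / 431),
    age_mean       = c(64.5, 61.3, 63.2),
    age_sd         = c(8.2, 9.9, 11.6),
    smoker_frac    = c(58 / 350, 102 / 698, 71 / 431),
    duration_mean  = c(13.9, 10.3, 13.1),
    duration_sd    = c(9.2, 8.8, 10.1),
    bmi_mean       = c(30.1, 31.0, 30.0),
    bmi_sd         = c(4.8, 5.7, 6.1),
    hba1c_mean     = c(8.6, 8.7, 9.1),
    hba1c_sd       = c(1.9, 2.0, 2.2),
    insulin_frac   = c(191 / 350, 271 / 698, 157 / 431),
    antihyp_frac   = c(296 / 350, 323 / 698, 291 / 431),
    antidyslip_frac = c(227 / 350, 195 / 698, 162 / 431),
    resistin_mean  = c(10.7, 10.1, 8.5),
    resistin_sd    = c(6.7, 8.1, 6.2),
    # incidence-rate target: printed events / printed person-years
    ir_target      = 100 * c(78 / 1890, 206 / 7504, 119 / 3060),
    followup_mean  = c(1890 / 350, 7504 / 698, 3060 / 431),
    # uniform(h - j, h + j) jitter matching the printed follow-up SD
    followup_jitter = sqrt(3) * c(2.5, 3.5, 2.5),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration for the synthetic multi-cohort generator
#'
#' Builds the full parameterization of the synthetic data generator. The
#' causal structure is: two independent bi-allelic SNPs raise mean
#' log-resistin additively; standardized log-resistin raises the log
#' hazard of death; a set of clinical covariates (confounders) affects
#' both log-resistin and the hazard, while remaining independent of the
#' genotypes, so the risk score stays a valid instrument.
#'
#' @param cohorts data.frame of per-cohort specifications, see
#'   [default_cohort_specs()] for the required columns.
#' @param maf1,maf2 risk-allele frequencies of the two SNPs, in \[0, 1\].
#' @param allele_effects length-2 numeric: additive effect of each risk
#'   allele on mean log-resistin (log ng/ml per allele).
#' @param score_jump extra mean log-resistin for carriers of 3 or more
#'   risk alleles (0 = purely additive genetics; positive values create
#'   the step-shaped dose-response used for coding-selection studies).
#' @param resistin_sigma residual SD of log-resistin. `NULL` (default)
#'   calibrates it per cohort so the raw-scale resistin mean and SD match
#'   the cohort targets under a log-normal model.
#' @param confounders_on_resistin named numeric vector of covariate
#'   effects on log-resistin (names among `age`, `male`, `smoker`, `bmi`,
#'   `hba1c`, `duration`, `insulin`, `antihyp`, `antidyslip`).
#' @param confounders_on_hazard named numeric vector of covariate effects
#'   on the log hazard (same name set).
#' @param causal_loghr_per_sd true causal effect of one SD of log-resistin
#'   on the log hazard of death.
#' @param survival_family `"exponential"` (default) or `"weibull"`.
#' @param weibull_shape shape parameter when `survival_family = "weibull"`
#'   (1 recovers the exponential).
#' @param missing_geno_frac fraction of genotype calls set to missing,
#'   independently per SNP and subject (default 0; 0.02 is a realistic
#'   value for exercising the complete-case exclusion policy).
#' @param calibrate_rates divide the baseline hazard by the analytic
#'   mean of `exp(linear predictor)` so the marginal incidence rate
#'   matches `ir_target` whatever the effect sizes (default `TRUE`).
#'   With `FALSE` the baseline rate is `ir_target / 100` itself, so
#'   strengthening any effect raises the expected event count.
#' @param seed integer seed stored with the configuration and used by the
#'   simulation entry points unless overridden.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$cohorts$label
#' @export
sim_config <- function(cohorts = default_cohort_specs(),
                       maf1 = 0.30,
                       maf2 = 0.37,
                       allele_effects = c(0.12, 0.12),
                       score_jump = 0,
                       resistin_sigma = NULL,
                       confounders_on_resistin = c(age = 0.004, male = 0.05,
                                                   smoker = 0.04, bmi = 0.006),
                       confounders_on_hazard = c(age = 0.03, male = 0.25,
                                                 smoker = 0.25, bmi = 0.01,
                                                 hba1c = 0.04, duration = 0.015),
                       causal_loghr_per_sd = log(1.27),
                       survival_family = c("exponential", "weibull"),
                       weibull_shape = 1,
                       missing_geno_frac = 0,
                       calibrate_rates = TRUE,
                       seed = 20170303L) {
  survival_family <- match.arg(survival_family)
  cfg <- structure(list(
    cohorts = cohorts,
    maf1 = maf1, maf2 = maf2,
    allele_effects = allele_effects,
    score_jump = score_jump,
    resistin_sigma = resistin_sigma,
    confounders_on_resistin = confounders_on_resistin,
    confounders_on_hazard = confounders_on_hazard,
    causal_loghr_per_sd = causal_loghr_per_sd,
    survival_family = survival_family,
    weibull_shape = weibull_shape,
    missing_geno_frac = missing_geno_frac,
    calibrate_rates = isTRUE(calibrate_rates),
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  co <- cfg$cohorts
  required <- c("label", "n", "male_frac", "age_mean", "age_sd", "smoker_frac",
                "duration_mean", "duration_sd", "bmi_mean", "bmi_sd",
                "hba1c_mean", "hba1c_sd", "insulin_frac", "antihyp_frac",
                "antidyslip_frac", "resistin_mean", "resistin_sd",
                "ir_target", "followup_mean", "followup_jitter")
  missing_cols <- setdiff(required, names(co))
  if (length(missing_cols) > 0)
    stop("cohort specification lacks columns: ",
         paste(missing_cols, collapse = ", "))
  if (nrow(co) < 1) stop("at least one cohort specification is required")
  if (anyDuplicated(co$label)) stop("duplicate cohort labels")
  if (any(co$n <= 0)) stop("all cohort sizes must be positive")
  if (any(co$ir_target <= 0)) stop("incidence-rate targets must be positive")
  if (any(co$resistin_mean <= 0) || any(co$resistin_sd <= 0))
    stop("resistin mean/SD targets must be positive")
  for (m in c(cfg$maf1, cfg$maf2))
    if (!is.finite(m) || m < 0 || m > 1)
      stop("minor-allele frequencies must lie in [0, 1]")
  if (length(cfg$allele_effects) != 2)
    stop("allele_effects must have length 2")
  if (!is.null(cfg$resistin_sigma) && cfg$resistin_sigma <= 0)
    stop("resistin_sigma must be positive")
  if (cfg$weibull_shape <= 0) stop("weibull_shape must be positive")
  if (cfg$missing_geno_frac < 0 || cfg$missing_geno_frac >= 1)
    stop("missing_geno_frac must lie in [0, 1)")
  invisible(cfg)
}

#' Read a simulation configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [sim_config()]; the `cohorts`
#' key holds a list of per-cohort mappings. Keys that are absent keep
#' their defaults.
#'
#' @param path path to a YAML file.
#' @return A `sim_config` object.
#' @export
sim_config_from_yaml <- function(path) {
  # keep bare keys like "n" or "y" as strings rather than YAML booleans
  raw <- yaml::read_yaml(path, handlers = list(
    "bool#yes" = function(x) if (toupper(x) %in% c("TRUE", "YES")) TRUE else x,
    "bool#no" = function(x) if (toupper(x) %in% c("FALSE", "NO")) FALSE else x))
  args <- raw
  if (!is.null(raw$cohorts)) {
    args$cohorts <- do.call(rbind, lapply(raw$cohorts, function(row)
      as.data.frame(row, stringsAsFactors = FALSE)))
  }
  if (!is.null(raw$confounders_on_resistin))
    args$confounders_on_resistin <- unlist(raw$confounders_on_resistin)
  if (!is.null(raw$confounders_on_hazard))
    args$confounders_on_hazard <- unlist(raw$confounders_on_hazard)
  if (!is.null(raw$allele_effects))
    args$allele_effects <- unlist(raw$allele_effects)
  do.call(sim_config, args)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic multi-cohort simulation configuration\n")
  cat(sprintf("  cohorts: %s (total n = %d)\n",
              paste(x$cohorts$label, collapse = ", "), sum(x$cohorts$n)))
  cat(sprintf("  risk-allele frequencies: %.2f, %.2f\n", x$maf1, x$maf2))
  cat(sprintf("  allele effects on log-resistin: %.3f, %.3f (jump at 3+: %.3f)\n",
              x$allele_effects[1], x$allele_effects[2], x$score_jump))
  cat(sprintf("  causal log-HR per SD of log-resistin: %.4f (HR %.3f)\n",
              x$causal_loghr_per_sd, exp(x$causal_loghr_per_sd)))
  cat(sprintf("  survival family: %s; missing genotype fraction: %.3f; seed: %d\n",
              x$survival_family, x$missing_geno_frac, x$seed))
  invisible(x)
}
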