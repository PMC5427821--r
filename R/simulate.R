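#' Simulate genotypes at a bi-allelic locus under Hardy-Weinberg equilibrium
#'
#' Risk-allele counts are drawn as Binomial(2, maf), so genotype
#' frequencies converge to \eqn{(1-p)^2, 2p(1-p), p^2}.
#'
#' @param n number of subjects.
#' @param maf risk-allele frequency in \[0, 1\].
#' @param seed optional integer seed; `NULL` leaves the RNG state alone.
#' @return Integer vector of allele counts in \{0, 1, 2\}.
#' @examples
#' table(simulate_genotypes(1000, 0.3, seed = 1))
#' @export
simulate_genotypes <- function(n, maf, seed = NULL) {
  if (!is.finite(maf) || maf < 0 || maf > 1)
    stop("maf must lie in [0, 1]")
  if (n < 1) stop("n must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  stats::rbinom(n, size = 2L, prob = maf)
}

# joint distribution of (g1, g2) and the genetic contribution to mean
# log-resistin, including the optional jump for carriers of 3+ alleles
.genetic_grid <- function(cfg) {
  g <- expand.grid(g1 = 0:2, g2 = 0:2)
  g$p <- stats::dbinom(g$g1, 2, cfg$maf1) * stats::dbinom(g$g2, 2, cfg$maf2)
  g$effect <- cfg$allele_effects[1] * g$g1 + cfg$allele_effects[2] * g$g2 +
    cfg$score_jump * as.numeric(g$g1 + g$g2 >= 3)
  g
}

# covariate metadata for one cohort row: distribution family, mean, var
.covariate_meta <- function(spec_row) {
  list(
    age       = list(type = "normal", mean = spec_row$age_mean,      var = spec_row$age_sd^2),
    male      = list(type = "bernoulli", mean = spec_row$male_frac,  var = spec_row$male_frac * (1 - spec_row$male_frac)),
    smoker    = list(type = "bernoulli", mean = spec_row$smoker_frac, var = spec_row$smoker_frac * (1 - spec_row$smoker_frac)),
    duration  = list(type = "normal", mean = spec_row$duration_mean, var = spec_row$duration_sd^2),
    bmi       = list(type = "normal", mean = spec_row$bmi_mean,      var = spec_row$bmi_sd^2),
    hba1c     = list(type = "normal", mean = spec_row$hba1c_mean,    var = spec_row$hba1c_sd^2),
    insulin   = list(type = "bernoulli", mean = spec_row$insulin_frac, var = spec_row$insulin_frac * (1 - spec_row$insulin_frac)),
    antihyp   = list(type = "bernoulli", mean = spec_row$antihyp_frac, var = spec_row$antihyp_frac * (1 - spec_row$antihyp_frac)),
    antidyslip = list(type = "bernoulli", mean = spec_row$antidyslip_frac, var = spec_row$antidyslip_frac * (1 - spec_row$antidyslip_frac))
  )
}

# Derived generator parameters for one cohort: log-resistin moments,
# residual SD, baseline hazard rate and censoring horizon.
#
# Raw-scale resistin targets (mean m, SD s) are matched by a log-normal:
# total log-variance v = log(1 + s^2/m^2), mean log mu = log(m) - v/2.
# The residual SD absorbs whatever variance the genetic and confounder
# terms do not account for. The baseline exponential rate is the target
# incidence rate divided by E[exp(eta)] of the hazard linear predictor,
# computed exactly from the component moment-generating functions.
.cohort_params <- function(cfg, label, sigma_lr) {
  spec <- cfg$cohorts[cfg$cohorts$label == label, , drop = FALSE]
  if (nrow(spec) != 1) stop("unknown cohort label: ", label)
  meta <- .covariate_meta(spec)
  grid <- .genetic_grid(cfg)

  v_total <- log(1 + (spec$resistin_sd / spec$resistin_mean)^2)
  mu_log <- log(spec$resistin_mean) - v_total / 2

  gen_mean <- sum(grid$p * grid$effect)
  gen_var <- sum(grid$p * grid$effect^2) - gen_mean^2
  delta <- cfg$confounders_on_resistin
  conf_var <- sum(vapply(names(delta), function(k)
    delta[[k]]^2 * meta[[k]]$var, numeric(1)))

  if (is.null(cfg$resistin_sigma)) {
    eps_var <- v_total - gen_var - conf_var
    if (eps_var <= 0)
      stop("genetic + confounder variance exceeds the target log-resistin ",
           "variance in cohort ", label,
           "; reduce allele/confounder effects or set resistin_sigma")
    sigma_eps <- sqrt(eps_var)
  } else {
    sigma_eps <- cfg$resistin_sigma
    v_total <- gen_var + conf_var + sigma_eps^2
    mu_log <- log(spec$resistin_mean) - v_total / 2
  }

  intercept <- mu_log - gen_mean

  # E[exp(eta)] of the hazard linear predictor; eta combines the causal
  # term beta_z * (logR - mu)/sigma_lr with direct confounder effects, so
  # each covariate's combined coefficient is gamma_k + beta_z*delta_k/sigma_lr
  beta_z <- cfg$causal_loghr_per_sd
  gamma <- cfg$confounders_on_hazard
  covs <- union(names(delta), names(gamma))
  mgf <- 1
  for (k in covs) {
    ck <- (if (k %in% names(gamma)) gamma[[k]] else 0) +
      beta_z * (if (k %in% names(delta)) delta[[k]] else 0) / sigma_lr
    m <- meta[[k]]
    mgf <- mgf * if (m$type == "normal") exp(ck^2 * m$var / 2)
                 else exp(-ck * m$mean) * (1 - m$mean + m$mean * exp(ck))
  }
  tg <- beta_z / sigma_lr
  mgf <- mgf * sum(grid$p * exp(tg * (grid$effect - gen_mean)))
  mgf <- mgf * exp((beta_z * sigma_eps / sigma_lr)^2 / 2)

  lambda_target <- spec$ir_target / 100
  rate0 <- if (isTRUE(cfg$calibrate_rates)) lambda_target / mgf
           else lambda_target
  if (cfg$survival_family == "weibull")
    rate0 <- rate0 * spec$followup_mean^(1 - cfg$weibull_shape)

  horizon <- .solve_horizon(lambda_target, spec$followup_mean, spec$followup_jitter)

  list(spec = spec, meta = meta, mu_log = mu_log, sigma_eps = sigma_eps,
       intercept = intercept, rate0 = rate0, horizon = horizon,
       lambda_target = lambda_target)
}

# E[min(T, C)] for T ~ Exp(lambda), C ~ Uniform(a, b), closed form
.e_min_exp_unif <- function(lambda, a, b) {
  if (a < 0) a <- 0
  ea <- exp(-lambda * a); eb <- exp(-lambda * b)
  (1 - ea) / lambda +
    (b * (ea - eb) / lambda -
       ((a / lambda + 1 / lambda^2) * ea - (b / lambda + 1 / lambda^2) * eb)) /
    (b - a)
}

# censoring-horizon midpoint h such that expected follow-up under the
# target event rate matches the target mean follow-up
.solve_horizon <- function(lambda, target_mean, jitter) {
  f <- function(h) .e_min_exp_unif(lambda, h - jitter, h + jitter) - target_mean
  stats::uniroot(f, lower = max(jitter, target_mean) + 1e-6,
                 upper = 100, tol = 1e-10)$root
}

# pooled (cohort-size weighted) theoretical SD of log-resistin, used to
# standardize the causal term inside the generator's hazard
.sigma_lr <- function(cfg) {
  co <- cfg$cohorts
  v <- vapply(seq_len(nrow(co)), function(i) {
    if (is.null(cfg$resistin_sigma))
      return(log(1 + (co$resistin_sd[i] / co$resistin_mean[i])^2))
    spec <- co[i, , drop = FALSE]
    meta <- .covariate_meta(spec)
    grid <- .genetic_grid(cfg)
    gen_mean <- sum(grid$p * grid$effect)
    gen_var <- sum(grid$p * grid$effect^2) - gen_mean^2
    delta <- cfg$confounders_on_resistin
    conf_var <- sum(vapply(names(delta), function(k)
      delta[[k]]^2 * meta[[k]]$var, numeric(1)))
    gen_var + conf_var + cfg$resistin_sigma^2
  }, numeric(1))
  sqrt(sum(co$n * v) / sum(co$n))
}

# generates one cohort from the current RNG state (no seeding here)
.gen_cohort <- function(cfg, label, sigma_lr) {
  par <- .cohort_params(cfg, label, sigma_lr)
  spec <- par$spec
  n <- spec$n

  male     <- stats::rbinom(n, 1, spec$male_frac) == 1
  age      <- stats::rnorm(n, spec$age_mean, spec$age_sd)
  smoker   <- stats::rbinom(n, 1, spec$smoker_frac) == 1
  duration <- pmax(stats::rnorm(n, spec$duration_mean, spec$duration_sd), 0)
  bmi      <- stats::rnorm(n, spec$bmi_mean, spec$bmi_sd)
  hba1c    <- stats::rnorm(n, spec$hba1c_mean, spec$hba1c_sd)
  insulin  <- stats::rbinom(n, 1, spec$insulin_frac) == 1
  antihyp  <- stats::rbinom(n, 1, spec$antihyp_frac) == 1
  antidyslip <- stats::rbinom(n, 1, spec$antidyslip_frac) == 1
  g1 <- stats::rbinom(n, 2, cfg$maf1)
  g2 <- stats::rbinom(n, 2, cfg$maf2)

  X <- list(age = age, male = as.numeric(male), smoker = as.numeric(smoker),
            duration = duration, bmi = bmi, hba1c = hba1c,
            insulin = as.numeric(insulin), antihyp = as.numeric(antihyp),
            antidyslip = as.numeric(antidyslip))

  delta <- cfg$confounders_on_resistin
  conf_lr <- rowSums(vapply(names(delta), function(k)
    delta[[k]] * (X[[k]] - par$meta[[k]]$mean), numeric(n)))
  log_res <- par$intercept +
    cfg$allele_effects[1] * g1 + cfg$allele_effects[2] * g2 +
    cfg$score_jump * as.numeric(g1 + g2 >= 3) +
    conf_lr + stats::rnorm(n, 0, par$sigma_eps)

  gamma <- cfg$confounders_on_hazard
  conf_hz <- rowSums(vapply(names(gamma), function(k)
    gamma[[k]] * (X[[k]] - par$meta[[k]]$mean), numeric(n)))
  z_true <- (log_res - par$mu_log) / sigma_lr
  eta <- cfg$causal_loghr_per_sd * z_true + conf_hz

  e_std <- stats::rexp(n)               # unit-exponential event draws
  t_event <- if (cfg$survival_family == "exponential") {
    e_std / (par$rate0 * exp(eta))
  } else {
    (e_std / (par$rate0 * exp(eta)))^(1 / cfg$weibull_shape)
  }
  censor <- stats::runif(n, max(par$horizon - spec$followup_jitter, 0),
                         par$horizon + spec$followup_jitter)
  follow_up <- pmin(t_event, censor)
  event <- t_event <= censor

  if (cfg$missing_geno_frac > 0) {
    g1[stats::runif(n) < cfg$missing_geno_frac] <- NA_integer_
    g2[stats::runif(n) < cfg$missing_geno_frac] <- NA_integer_
  }

  data.frame(
    subject_id = sprintf("%s-%04d", label, seq_len(n)),
    cohort = label,
    sex = ifelse(male, "male", "female"),
    age_at_recruitment = age,
    smoker = smoker,
    diabetes_duration = duration,
    bmi = bmi,
    hba1c = hba1c,
    insulin_therapy = insulin,
    antihypertensive = antihyp,
    antidyslipidemia = antidyslip,
    resistin = exp(log_res),
    g1 = as.integer(g1),
    g2 = as.integer(g2),
    follow_up = follow_up,
    event = event,
    stringsAsFactors = FALSE
  )
}

#' Simulate a single synthetic cohort
#'
#' Covariates are drawn from the per-cohort distributions of the
#' configuration; log-resistin is intercept + additive allele effects +
#' confounder terms + Gaussian noise; death times follow an exponential
#' (or Weibull) hazard with log-hazard = baseline +
#' `causal_loghr_per_sd` x standardized log-resistin + confounder terms;
#' follow-up is the minimum of the event time and a uniform
#' administrative censoring time.
#'
#' @param config a [sim_config()] object.
#' @param cohort_label one of `config$cohorts$label`.
#' @param seed integer seed (defaults to the seed stored in the config).
#' @return A data.frame with one row per subject (see the package
#'   vignette for the column schema).
#' @examples
#' d <- simulate_cohort(sim_config(seed = 1), "GHS")
#' nrow(d)
#' @export
simulate_cohort <- function(config, cohort_label, seed = config$seed) {
  validate_sim_config(config)
  if (!cohort_label %in% config$cohorts$label)
    stop("unknown cohort label: ", cohort_label)
  set.seed(seed)
  .gen_cohort(config, cohort_label, .sigma_lr(config))
}

#' Simulate the full multi-cohort dataset
#'
#' Concatenates per-cohort tables in the order the cohorts appear in the
#' configuration; the default configuration yields 350 + 698 + 431 =
#' 1,479 rows.
#'
#' @inheritParams simulate_cohort
#' @return A data.frame with one row per subject across all cohorts.
#' @examples
#' d <- simulate_multi_cohort(sim_config(seed = 1))
#' table(d$cohort)
#' @export
simulate_multi_cohort <- function(config, seed = config$seed) {
  validate_sim_config(config)
  set.seed(seed)
  sigma_lr <- .sigma_lr(config)
  out <- do.call(rbind, lapply(config$cohorts$label, function(lab)
    .gen_cohort(config, lab, sigma_lr)))
  rownames(out) <- NULL
  out
}

#' Write a cohort table as delimited text
#'
#' Comma-separated, header row, UTF-8, missing values as empty fields.
#'
#' @param table a cohort data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}
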