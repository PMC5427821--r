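#' Read a cohort table from delimited text
#'
#' Comma-separated with header; empty fields are missing values. The
#' required schema matches what [write_cohort_csv()] produces; extra
#' columns are tolerated and noted in the validation report.
#'
#' @param path input file path.
#' @return The typed cohort data.frame, with a `validation` attribute
#'   (row count, missingness per column, extra columns).
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  required <- c("subject_id", "cohort", "sex", "age_at_recruitment",
                "smoker", "diabetes_duration", "bmi", "hba1c",
                "insulin_therapy", "antihypertensive", "antidyslipidemia",
                "resistin", "g1", "g2", "follow_up", "event")
  raw <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0)
    stop("schema error, missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(raw), required)

  for (col in c("smoker", "insulin_therapy", "antihypertensive",
                "antidyslipidemia", "event"))
    raw[[col]] <- as.logical(raw[[col]])
  for (col in c("g1", "g2")) {
    v <- raw[[col]]
    bad <- !is.na(v) & !v %in% 0:2
    if (any(bad))
      stop("unparseable genotype in column ", col, ", row(s): ",
           paste(utils::head(which(bad), 5), collapse = ", "))
    raw[[col]] <- as.integer(v)
  }
  bad_res <- which(!is.na(raw$resistin) & raw$resistin <= 0)
  if (length(bad_res) > 0)
    stop("nonpositive resistin value(s) at row(s): ",
         paste(utils::head(bad_res, 5), collapse = ", "))
  if (any(!is.na(raw$follow_up) & raw$follow_up < 0))
    stop("negative follow-up times")

  attr(raw, "validation") <- list(
    n = nrow(raw),
    missing_per_column = vapply(raw, function(x) sum(is.na(x)), integer(1)),
    extra_columns = extra
  )
  raw
}

#' Per-cohort descriptive table
#'
#' Means and SDs of continuous covariates, percentages of binary ones,
#' events, person-years and the incidence rate per 100 person-years —
#' per cohort and combined.
#'
#' @param table cohort data.frame.
#' @return data.frame with one row per cohort plus a combined row.
#' @export
cohort_descriptives <- function(table) {
  one <- function(d, label) {
    data.frame(
      cohort = label, n = nrow(d),
      male_pct = 100 * mean(d$sex == "male"),
      age_mean = mean(d$age_at_recruitment), age_sd = stats::sd(d$age_at_recruitment),
      smoker_pct = 100 * mean(d$smoker),
      duration_mean = mean(d$diabetes_duration), duration_sd = stats::sd(d$diabetes_duration),
      bmi_mean = mean(d$bmi), bmi_sd = stats::sd(d$bmi),
      hba1c_mean = mean(d$hba1c), hba1c_sd = stats::sd(d$hba1c),
      insulin_pct = 100 * mean(d$insulin_therapy),
      antihyp_pct = 100 * mean(d$antihypertensive),
      antidyslip_pct = 100 * mean(d$antidyslipidemia),
      resistin_mean = mean(d$resistin, na.rm = TRUE),
      resistin_sd = stats::sd(d$resistin, na.rm = TRUE),
      followup_mean = mean(d$follow_up), followup_sd = stats::sd(d$follow_up),
      person_years = person_years(d),
      events = sum(d$event),
      incidence_rate = incidence_rate(sum(d$event), person_years(d)),
      stringsAsFactors = FALSE
    )
  }
  rows <- lapply(unique(table$cohort), function(co)
    one(table[table$cohort == co, , drop = FALSE], co))
  rows[[length(rows) + 1]] <- one(table, "combined")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Published summary statistics of the motivating three-cohort study
#'
#' The subject-level data of the motivating study of serum resistin and
#' all-cause mortality in type 2 diabetes were never deposited; its
#' published summary statistics are shipped here so the summary-level
#' replication surface ([replicate_from_summaries()]) needs no external
#' input. Contents: per-cohort Model-1 hazard ratios per SD of
#' log-resistin with 95% CIs, the fully adjusted combined estimate, the
#' causal (instrumental-variable) estimate, per-cohort events and
#' person-years, and the pooled risk-score category counts.
#'
#' @return list with `model1` (data.frame), `observed_model3`,
#'   `causal`, `cohorts` (events/person-years), `grs_counts`.
#' @export
reference_summaries <- function() {
  list(
    model1 = data.frame(
      cohort = c("GHS", "GMS", "FMS"),
      hr = c(1.55, 1.38, 1.31),
      lo = c(1.27, 1.21, 1.11),
      hi = c(1.90, 1.57, 1.56),
      stringsAsFactors = FALSE
    ),
    observed_model3 = c(hr = 1.27, lo = 1.14, hi = 1.41),
    causal = c(hr = 2.17, lo = 1.22, hi = 3.87),
    cohorts = data.frame(
      cohort = c("GHS", "GMS", "FMS"),
      n = c(350L, 698L, 431L),
      events = c(78L, 206L, 119L),
      person_years = c(1890, 7504, 3060),
      stringsAsFactors = FALSE
    ),
    grs_counts = c(`0` = 231L, `1` = 587L, `2` = 599L, `3` = 60L, `4` = 2L)
  )
}

#' Summary-statistics replication of the published analysis
#'
#' Requires no subject-level data and no randomness: pools the published
#' per-cohort Model-1 estimates by inverse variance, computes the
#' between-study Cochran Q, the per-cohort and combined incidence rates,
#' the causal-versus-observed Cochran Q, and the analytic power
#' quantities (detectable HRs per SD and per risk allele, detectable
#' stage-1 slope) at the published event count.
#'
#' @param summaries a list shaped like [reference_summaries()] (the
#'   default).
#' @param alpha,power settings for the power section.
#' @return list with `pooled_model1`, `heterogeneity`, `incidence`,
#'   `total_person_years`, `causal_vs_observed`, `grs_variance`, and
#'   `power`.
#' @export
replicate_from_summaries <- function(summaries = reference_summaries(),
                                     alpha = 0.05, power = 0.80) {
  m1 <- summaries$model1
  eff <- mapply(function(h, l, u) unlist(se_from_ci(h, l, u)),
                m1$hr, m1$lo, m1$hi)
  est <- eff["estimate", ]; se <- eff["se", ]
  pooled <- pool_fixed_effect(est, se)
  het <- heterogeneity_q(est, se)

  obs <- se_from_ci(summaries$observed_model3[["hr"]],
                    summaries$observed_model3[["lo"]],
                    summaries$observed_model3[["hi"]])
  cau <- se_from_ci(summaries$causal[["hr"]],
                    summaries$causal[["lo"]],
                    summaries$causal[["hi"]])
  qcmp <- causal_vs_observed_q(cau$estimate, cau$se, obs$estimate, obs$se)

  co <- summaries$cohorts
  inc <- data.frame(
    cohort = c(co$cohort, "combined"),
    events = c(co$events, sum(co$events)),
    person_years = c(co$person_years, sum(co$person_years)),
    stringsAsFactors = FALSE
  )
  inc$incidence_rate <- incidence_rate(inc$events, inc$person_years)

  counts <- summaries$grs_counts
  scores <- as.numeric(names(counts))
  ntot <- sum(counts)
  mean_s <- sum(scores * counts) / ntot
  var_s <- (sum(scores^2 * counts) - ntot * mean_s^2) / (ntot - 1)
  total_events <- sum(co$events)

  list(
    pooled_model1 = pooled,
    heterogeneity = het,
    incidence = inc,
    total_person_years = sum(co$person_years),
    causal_vs_observed = qcmp,
    grs_variance = var_s,
    power = list(
      detectable_hr_per_sd = detectable_hr(total_events, alpha, power, 1),
      detectable_hr_per_allele = detectable_hr(total_events, alpha, power, var_s),
      detectable_slope = detectable_slope(ntot, alpha, power, var_s, 1),
      events = total_events, alpha = alpha, power = power
    )
  )
}

#' Run the full analysis pipeline
#'
#' Executes the analysis sequence on a subject-level cohort table:
#' descriptives; resistin standardization; resistin-mortality Cox
#' Models 1-3 per cohort and combined with heterogeneity testing and the
#' robust-CI rule; Hardy-Weinberg QC; risk-score construction and
#' confounder balance; exposure-stage models with AIC coding selection
#' and percent-change estimates; risk-score-mortality models; the
#' supremum log-linearity check; the causal instrumental-variable
#' estimates with the Cochran Q comparison; and the power section. If
#' the genotype columns are absent or empty the genetic stages are
#' skipped and the causal section is marked not computed.
#'
#' @param table cohort data.frame (e.g. from [simulate_multi_cohort()]
#'   or [read_cohort_csv()]).
#' @param seed integer seed driving the simulation-based supremum test.
#' @param n_sim_supremum simulated residual patterns for the supremum
#'   test (default 10,000).
#' @param m3_covariates Model-3 adjustment set, also used by the causal
#'   stages.
#' @param verbose log stage progress to standard error.
#' @return A list of class `mr_report`.
#' @export
run_all <- function(table, seed = 1L, n_sim_supremum = 10000,
                    m3_covariates = c("sex", "age_at_recruitment", "smoker",
                                      "bmi", "hba1c", "antihypertensive",
                                      "antidyslipidemia"),
                    verbose = FALSE) {
  say <- function(...) if (verbose) message("[run_all] ", ...)
  report <- list(seed = as.integer(seed))

  say("descriptives")
  report$descriptives <- cohort_descriptives(table)

  say("resistin standardization")
  z <- standardize_resistin(table$resistin)
  report$log_resistin_sd <- attr(z, "sd")

  say("resistin-mortality models 1-3")
  report$observational <- model_suite(table, as.numeric(z))

  has_geno <- all(c("g1", "g2") %in% names(table)) &&
    any(!is.na(table$g1) & !is.na(table$g2))
  if (!has_geno) {
    say("no genotypes: genetic stages skipped")
    report$causal <- list(computed = FALSE,
                          reason = "genotype columns absent or empty")
    class(report) <- "mr_report"
    return(report)
  }

  say("Hardy-Weinberg QC")
  hwe_rows <- list()
  for (snp in c("g1", "g2")) {
    for (co in c(unique(table$cohort), "combined")) {
      g <- if (co == "combined") table[[snp]]
           else table[[snp]][table$cohort == co]
      ct <- genotype_counts(g)
      h <- hwe_test(ct[1], ct[2], ct[3])
      hwe_rows[[length(hwe_rows) + 1]] <-
        data.frame(snp = snp, cohort = co, chisq = h$chisq, p = h$p,
                   maf = h$maf, stringsAsFactors = FALSE)
    }
  }
  report$hwe <- do.call(rbind, hwe_rows)

  say("risk score")
  grs <- build_grs(table)
  report$grs_counts <- grs$category_counts
  report$grs_excluded <- grs$n_excluded

  say("confounder balance")
  report$confounder_balance <- confounder_balance(
    table, grs, c("age_at_recruitment", "sex", "smoker", "bmi", "hba1c",
                  "antihypertensive", "antidyslipidemia"))

  say("per-SNP exposure effects (Bonferroni 0.025)")
  snp_rows <- lapply(c("g1", "g2"), function(snp) {
    keep <- !is.na(table[[snp]]) & !is.na(table$resistin)
    d <- table[keep, , drop = FALSE]
    zz <- standardize_resistin(d$resistin)
    df <- .analysis_frame(d, as.numeric(zz), covariates = m3_covariates)
    df$g <- d[[snp]]
    fit <- stats::lm(.y ~ ., data = df)
    sm <- summary(fit)$coefficients["g", ]
    data.frame(snp = snp, beta_per_allele = sm[["Estimate"]],
               se = sm[["Std. Error"]], p = sm[["Pr(>|t|)"]],
               bonferroni_significant = sm[["Pr(>|t|)"]] < 0.025,
               stringsAsFactors = FALSE)
  })
  report$per_snp_exposure <- do.call(rbind, snp_rows)

  say("exposure models (AIC coding selection)")
  complete <- !is.na(grs$score) & !is.na(table$resistin)
  tab_g <- table[complete, , drop = FALSE]
  grs_g <- build_grs(tab_g)
  fit_cat <- fit_exposure_model(tab_g, grs_g, "categorical", m3_covariates)
  fit_cont <- fit_exposure_model(tab_g, grs_g, "continuous", m3_covariates)
  chosen <- compare_codings(fit_cat, fit_cont)
  report$exposure <- list(
    aic = attr(chosen, "aic"),
    chosen_coding = attr(chosen, "chosen"),
    overall_p_categorical = fit_cat$overall_p,
    overall_p_continuous = fit_cont$overall_p,
    percent_change = percent_change_means(fit_cat)
  )

  say("risk-score-mortality models")
  report$grs_mortality <- list(
    categorical = model_suite(tab_g, grs_g$category),
    continuous = model_suite(tab_g, as.numeric(grs_g$score))
  )
  cox_cat <- fit_cox(tab_g, grs_g$category, m3_covariates)
  cox_cont <- fit_cox(tab_g, as.numeric(grs_g$score), m3_covariates)
  report$grs_mortality$aic <- c(categorical = cox_cat$aic,
                                continuous = cox_cont$aic)
  report$grs_mortality$chosen_coding <-
    if (cox_cat$aic < cox_cont$aic) "categorical" else "continuous"

  say("supremum log-linearity test")
  m1_fit <- fit_cox(table, as.numeric(z))
  report$supremum <- supremum_linearity_test(m1_fit, ".x",
                                             n_sim = n_sim_supremum,
                                             seed = seed)

  say("causal instrumental-variable estimates")
  ts <- two_stage_cox(tab_g, grs_g, m3_covariates)
  zz <- standardize_resistin(tab_g$resistin)
  s1 <- fit_exposure_model(tab_g, grs_g, "continuous", m3_covariates,
                           response = zz)
  s2 <- fit_cox(tab_g, as.numeric(grs_g$score), m3_covariates)
  wr <- wald_ratio(s1$coefficients[["grs"]],
                   sqrt(s1$vcov["grs", "grs"]),
                   s2$coefficients[[".x"]],
                   sqrt(s2$vcov[".x", ".x"]))
  obs_comb <- report$observational
  obs_row <- obs_comb[obs_comb$model == "3" & obs_comb$cohort == "combined", ]
  qcmp <- causal_vs_observed_q(ts$estimate, ts$se,
                               obs_row$estimate[1], obs_row$se[1])
  report$causal <- list(computed = TRUE, two_stage = ts, wald = wr,
                        q_vs_observed = qcmp)

  say("power section")
  total_events <- sum(table$event)
  counts <- as.numeric(report$grs_counts)
  # variance of the unpooled score among genotyped subjects
  sc <- grs$score[!is.na(grs$score)]
  report$power <- list(
    events = total_events,
    detectable_hr_per_sd = detectable_hr(total_events, 0.05, 0.80, 1),
    detectable_hr_per_allele = detectable_hr(total_events, 0.05, 0.80,
                                             stats::var(sc)),
    detectable_slope = detectable_slope(length(sc), 0.05, 0.80,
                                        stats::var(sc), 1)
  )

  report$provenance <- list(seed = as.integer(seed),
                            n = nrow(table),
                            package_version =
                              as.character(utils::packageVersion("resistinMR")))
  class(report) <- "mr_report"
  report
}

#' @export
print.mr_report <- function(x, ...) {
  cat("Resistin-mortality Mendelian randomization report\n")
  d <- x$descriptives
  cat(sprintf("  subjects: %d; events: %d; person-years: %.0f\n",
              d$n[d$cohort == "combined"], d$events[d$cohort == "combined"],
              d$person_years[d$cohort == "combined"]))
  obs <- x$observational
  for (m in c("1", "2", "3")) {
    r <- obs[obs$model == m & obs$cohort == "combined", ]
    if (nrow(r) == 1)
      cat(sprintf("  Model %s combined HR per SD: %.2f (%.2f-%.2f)%s\n",
                  m, r$hr, r$lo, r$hi, if (r$robust) " [robust]" else ""))
  }
  if (isTRUE(x$causal$computed)) {
    ts <- x$causal$two_stage
    cat(sprintf("  causal HR per SD (two-stage): %.2f (%.2f-%.2f); Q p = %.3g\n",
                ts$hr, ts$hr_lo, ts$hr_hi, x$causal$q_vs_observed$p))
  } else {
    cat("  causal section: not computed (", x$causal$reason, ")\n", sep = "")
  }
  invisible(x)
}

#' Export figure data: percent change of log-resistin mean and HR per
#' risk-score category
#'
#' One row per risk-score category with the percent change of the
#' adjusted log-resistin mean (with 95% CI) and the mortality hazard
#' ratio (with 95% CI), both referenced to the score-0 group; the
#' reference row is fixed at (0%, HR 1).
#'
#' @param report an [run_all()] report with the genetic stages computed.
#' @return data.frame with columns `category`, `percent_change`,
#'   `pc_lo`, `pc_hi`, `hr`, `hr_lo`, `hr_hi`.
#' @export
export_fig1_data <- function(report) {
  if (!isTRUE(report$causal$computed))
    stop("report lacks the genetic stages; figure data unavailable")
  pc <- report$exposure$percent_change
  hrtab <- report$grs_mortality$categorical
  hr3 <- hrtab[hrtab$model == "3" & hrtab$cohort == "combined", ]
  out <- data.frame(category = pc$category,
                    percent_change = pc$percent, pc_lo = pc$lo, pc_hi = pc$hi,
                    hr = NA_real_, hr_lo = NA_real_, hr_hi = NA_real_,
                    stringsAsFactors = FALSE)
  out$hr[out$category == "0"] <- 1
  out$hr_lo[out$category == "0"] <- 1
  out$hr_hi[out$category == "0"] <- 1
  for (i in seq_len(nrow(hr3))) {
    cat_i <- hr3$term[i]
    j <- which(out$category == cat_i)
    if (length(j) == 1) {
      out$hr[j] <- hr3$hr[i]; out$hr_lo[j] <- hr3$lo[i]; out$hr_hi[j] <- hr3$hi[i]
    }
  }
  out
}
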