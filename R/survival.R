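#' Fit a Cox proportional-hazards model
#'
#' Thin wrapper around [survival::coxph()] (Efron tie handling by
#' default) returning the pieces the rest of the pipeline needs:
#' coefficients with model-based and optionally robust (sandwich)
#' covariance, partial log-likelihood, AIC, and the Breslow baseline
#' cumulative hazard.
#'
#' @param table cohort data.frame with `follow_up` and `event` columns.
#' @param exposure a column name, or a numeric vector / factor of length
#'   `nrow(table)`.
#' @param covariates character vector of adjustment columns.
#' @param robust request the sandwich covariance.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param cohort_term include fixed cohort indicators when several
#'   cohorts are present (default `TRUE`).
#' @return Object of class `cox_fit`.
#' @export
fit_cox <- function(table, exposure, covariates = character(0),
                    robust = FALSE, ties = c("efron", "breslow"),
                    cohort_term = TRUE) {
  ties <- match.arg(ties)
  if (!all(c("follow_up", "event") %in% names(table)))
    stop("table must contain follow_up and event columns")
  if (any(!is.finite(table$follow_up)))
    stop("non-finite follow-up times at rows: ",
         paste(utils::head(which(!is.finite(table$follow_up)), 5), collapse = ", "))
  if (any(table$follow_up < 0)) stop("negative follow-up times")

  ex <- if (is.character(exposure) && length(exposure) == 1) {
    if (!exposure %in% names(table)) stop("exposure column missing: ", exposure)
    table[[exposure]]
  } else exposure
  exposure_name <- if (is.character(exposure) && length(exposure) == 1)
    exposure else "exposure"

  df <- .analysis_frame(table, as.numeric(table$follow_up),
                        covariates = covariates, cohort_term = cohort_term)
  names(df)[1] <- ".time"
  df$.status <- as.numeric(table$event)
  df$.x <- if (is.character(ex)) factor(ex) else ex
  keep <- stats::complete.cases(df)
  df <- df[keep, , drop = FALSE]
  if (is.factor(df$.x)) df$.x <- droplevels(df$.x)
  if (sum(df$.status) < 1) stop("no events in the data")

  rhs <- c(".x", covariates, if ("cohort" %in% names(df)) "cohort")
  form <- stats::reformulate(rhs, response = "survival::Surv(.time, .status)")
  fit <- survival::coxph(form, data = df, ties = ties, robust = robust,
                         x = TRUE, y = TRUE)

  vc_model <- if (robust && !is.null(fit$naive.var)) fit$naive.var else fit$var
  dimnames(vc_model) <- list(names(stats::coef(fit)), names(stats::coef(fit)))
  vc_robust <- if (robust) fit$var else NULL
  if (!is.null(vc_robust))
    dimnames(vc_robust) <- dimnames(vc_model)

  structure(list(
    coefficients = stats::coef(fit),
    vcov = vc_model,
    vcov_robust = vc_robust,
    robust = robust,
    loglik = fit$loglik[length(fit$loglik)],
    aic = stats::AIC(fit),
    n = fit$n,
    events = fit$nevent,
    ties = ties,
    exposure_name = exposure_name,
    basehaz = survival::basehaz(fit, centered = FALSE),
    coxph_fit = fit,
    data = df
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox fit (%s ties%s): n = %d, events = %d, AIC = %.1f\n",
              x$ties, if (x$robust) ", robust SE" else "", x$n, x$events, x$aic))
  se <- sqrt(diag(if (x$robust) x$vcov_robust else x$vcov))
  print(data.frame(coef = x$coefficients, hr = exp(x$coefficients), se = se))
  invisible(x)
}

# extract (estimate, se, p) rows for the exposure term(s) of a cox_fit
.cox_effects <- function(fit, label_prefix = "") {
  V <- if (fit$robust) fit$vcov_robust else fit$vcov
  idx <- grep("^\\.x", names(fit$coefficients))
  est <- fit$coefficients[idx]
  se <- sqrt(diag(V)[idx])
  zq <- stats::qnorm(0.975)
  term <- sub("^\\.x", "", names(est))
  term[term == ""] <- fit$exposure_name
  data.frame(
    term = paste0(label_prefix, term),
    estimate = unname(est), se = unname(se),
    hr = exp(unname(est)),
    lo = exp(unname(est) - zq * se), hi = exp(unname(est) + zq * se),
    p = 2 * stats::pnorm(-abs(unname(est) / se)),
    n = fit$n, events = fit$events, robust = fit$robust,
    stringsAsFactors = FALSE
  )
}

#' Cochran Q test of between-study heterogeneity
#'
#' Fixed-effect Q statistic \eqn{\sum w_i (\theta_i - \bar\theta)^2} with
#' inverse-variance weights \eqn{w_i = 1/SE_i^2} and
#' \eqn{\bar\theta = \sum w_i\theta_i / \sum w_i}; the p-value is
#' chi-square with k-1 degrees of freedom.
#'
#' @param estimate numeric vector of estimates on a common (log) scale.
#' @param se their standard errors.
#' @return list with `Q`, `df`, `p`.
#' @examples
#' heterogeneity_q(c(0.2, 0.2), c(0.1, 0.1))   # Q = 0, p = 1
#' @export
heterogeneity_q <- function(estimate, se) {
  if (length(estimate) < 2) stop("at least 2 estimates required")
  if (length(se) != length(estimate)) stop("estimate/se length mismatch")
  if (all(estimate == estimate[1]))
    return(list(Q = 0, df = length(estimate) - 1L, p = 1))
  if (any(se <= 0)) stop("zero or negative SE with differing estimates")
  w <- 1 / se^2
  theta <- sum(w * estimate) / sum(w)
  Q <- sum(w * (estimate - theta)^2)
  df <- length(estimate) - 1L
  list(Q = Q, df = df, p = stats::pchisq(Q, df, lower.tail = FALSE))
}

#' Fixed-effect (inverse-variance) pooling
#'
#' Pools estimates on the log scale: weighted mean with weights
#' \eqn{1/SE_i^2}, pooled SE \eqn{1/\sqrt{\sum w_i}}, normal 95% CI, and
#' a two-sided z-test p-value.
#'
#' @inheritParams heterogeneity_q
#' @return list with `estimate`, `se`, `lo`, `hi` (log scale), the
#'   exponentiated `hr`, `hr_lo`, `hr_hi`, and `p`.
#' @export
pool_fixed_effect <- function(estimate, se) {
  if (length(estimate) == 0) stop("no estimates to pool")
  if (any(se <= 0)) stop("standard errors must be positive")
  w <- 1 / se^2
  est <- sum(w * estimate) / sum(w)
  pooled_se <- 1 / sqrt(sum(w))
  zq <- stats::qnorm(0.975)
  list(estimate = est, se = pooled_se,
       lo = est - zq * pooled_se, hi = est + zq * pooled_se,
       hr = exp(est), hr_lo = exp(est - zq * pooled_se),
       hr_hi = exp(est + zq * pooled_se),
       p = 2 * stats::pnorm(-abs(est / pooled_se)))
}

#' Incidence rate per 100 person-years
#'
#' @param events number of events (vectorized).
#' @param person_years total follow-up in years (vectorized).
#' @return `100 * events / person_years`.
#' @examples
#' incidence_rate(78, 1890)   # 4.13
#' @export
incidence_rate <- function(events, person_years) {
  if (any(person_years <= 0)) stop("person_years must be positive")
  100 * events / person_years
}

#' Total person-years of a cohort table
#'
#' @param table data.frame with a `follow_up` column.
#' @return Sum of follow-up times.
#' @export
person_years <- function(table) {
  if (!"follow_up" %in% names(table)) stop("table lacks follow_up column")
  sum(table$follow_up)
}

#' Observational model suite (Models 1-3, per cohort and combined)
#'
#' Fits the three standard adjustment sets for a given exposure:
#' Model 1 unadjusted (cohort indicators in the combined analysis),
#' Model 2 adding sex, age at recruitment, smoking and BMI, Model 3
#' further adding HbA1c and anti-hypertension/anti-dyslipidemia
#' therapies. Fits are per cohort and combined; for scalar exposures the
#' combined fit switches to the robust sandwich covariance when the
#' between-study Cochran Q p-value falls below `robust_threshold`
#' (default 0.10).
#'
#' @param table cohort data.frame.
#' @param exposure column name or numeric vector / factor (e.g. the
#'   standardized log-resistin, the risk-score count, or the pooled
#'   risk-score category).
#' @param models subset of `c("1", "2", "3")`.
#' @param robust_threshold heterogeneity p-value below which the
#'   combined estimate uses robust confidence intervals.
#' @return data.frame of effect estimates (one row per term, model and
#'   cohort, plus combined rows carrying `het_q`/`het_p`).
#' @export
model_suite <- function(table, exposure, models = c("1", "2", "3"),
                        robust_threshold = 0.10) {
  adj <- list(
    "1" = character(0),
    "2" = c("sex", "age_at_recruitment", "smoker", "bmi"),
    "3" = c("sex", "age_at_recruitment", "smoker", "bmi", "hba1c",
            "antihypertensive", "antidyslipidemia")
  )
  ex <- if (is.character(exposure) && length(exposure) == 1)
    table[[exposure]] else exposure
  cohorts <- unique(table$cohort)
  out <- list()
  for (m in models) {
    covs <- adj[[m]]
    missing_cols <- setdiff(covs, names(table))
    if (length(missing_cols) > 0)
      stop("missing covariate column(s): ", paste(missing_cols, collapse = ", "))
    per_cohort <- list()
    for (co in cohorts) {
      sel <- table$cohort == co
      fit <- fit_cox(table[sel, , drop = FALSE],
                     if (is.factor(ex)) droplevels(ex[sel]) else ex[sel],
                     covariates = covs, cohort_term = FALSE)
      eff <- .cox_effects(fit)
      eff$model <- m; eff$cohort <- co
      per_cohort[[co]] <- eff
      out[[length(out) + 1]] <- eff
    }
    scalar <- !is.factor(ex)
    het <- NULL
    use_robust <- FALSE
    if (scalar && length(cohorts) >= 2) {
      ests <- vapply(per_cohort, function(e) e$estimate[1], numeric(1))
      ses <- vapply(per_cohort, function(e) e$se[1], numeric(1))
      het <- heterogeneity_q(ests, ses)
      use_robust <- het$p < robust_threshold
    }
    fit_c <- fit_cox(table, ex, covariates = covs, robust = use_robust,
                     cohort_term = TRUE)
    eff_c <- .cox_effects(fit_c)
    eff_c$model <- m; eff_c$cohort <- "combined"
    if (!is.null(het)) { eff_c$het_q <- het$Q; eff_c$het_p <- het$p }
    else { eff_c$het_q <- NA_real_; eff_c$het_p <- NA_real_ }
    out[[length(out) + 1]] <- eff_c
  }
  for (i in seq_along(out)) {
    if (!"het_q" %in% names(out[[i]])) {
      out[[i]]$het_q <- NA_real_; out[[i]]$het_p <- NA_real_
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# ---- supremum test of functional form -------------------------------------

# Breslow baseline cumulative hazard at each subject's own time, for an
# arbitrary coefficient vector beta (used by the numeric derivative of
# the cumulative-residual process)
.breslow_cumhaz <- function(time, status, lp) {
  w <- exp(lp)
  ot <- order(time)
  n <- length(time)
  # risk-set sums at each ordered time (ties share the risk set)
  w_ord <- w[ot]; t_ord <- time[ot]; s_ord <- status[ot]
  rs <- rev(cumsum(rev(w_ord)))
  # collapse ties: for tied times, risk set is that of the first index
  first_idx <- !duplicated(t_ord)
  ut <- t_ord[first_idx]
  rs_u <- rs[first_idx]
  d_u <- as.numeric(tapply(s_ord, match(t_ord, ut), sum))
  dl <- d_u / rs_u
  event_times <- ut[d_u > 0]
  dl <- dl[d_u > 0]
  cum <- cumsum(dl)
  # Lambda0 at each subject's time
  pos <- findInterval(time, event_times)
  L <- ifelse(pos == 0, 0, cum[pmax(pos, 1)])
  list(Lambda = L, event_times = event_times, dLambda = dl)
}

# cumulative martingale-residual process over the sorted covariate axis,
# at coefficient vector beta; returns W(x) at each sorted cut
.w_process <- function(time, status, Z, beta, x_order) {
  lp <- drop(Z %*% beta)
  bh <- .breslow_cumhaz(time, status, lp)
  M <- status - bh$Lambda * exp(lp)
  cumsum(M[x_order])
}

#' Kolmogorov-type supremum test of log-linearity
#'
#' Checks the functional form of a covariate in a Cox model with the
#' cumulative-martingale-residual process: per-subject martingale
#' residuals are summed over the sorted covariate axis, the observed
#' statistic is the supremum of the absolute cumulative process, and its
#' null distribution is obtained by resampling residual patterns, each
#' subject's contribution multiplied by an independent standard normal
#' draw.
#'
#' Two resampling schemes are available. `"simple"` multiplies the raw
#' residual indicator contributions. `"influence"` resamples the full
#' first-order influence decomposition: each subject's compensated
#' process contribution plus the score-residual term propagating the
#' uncertainty of the estimated coefficients (numerically differentiated
#' cumulative process); this is the scheme that matches the nominal
#' level in calibration simulations and is the default.
#'
#' @param fit a [fit_cox()] object containing the covariate.
#' @param covariate name of a numeric model column (e.g. `".x"` for the
#'   exposure passed to [fit_cox()]).
#' @param n_sim number of simulated residual patterns (default 10,000).
#' @param seed optional integer seed.
#' @param resample `"influence"` (default) or `"simple"`.
#' @return list with `statistic` (observed supremum), `p`, `n_sim`,
#'   `resample`, and the observed process (`x`, `W`).
#' @export
supremum_linearity_test <- function(fit, covariate = ".x", n_sim = 10000,
                                    seed = NULL,
                                    resample = c("influence", "simple")) {
  resample <- match.arg(resample)
  if (!inherits(fit, "cox_fit")) stop("fit must be a cox_fit object")
  if (n_sim < 100) stop("n_sim must be at least 100")
  if (!is.null(seed)) set.seed(seed)

  cox <- fit$coxph_fit
  Z <- cox$x
  time <- cox$y[, 1]; status <- cox$y[, 2]
  cn <- colnames(Z)
  xcol <- if (covariate %in% cn) covariate else grep(paste0("^", covariate),
                                                     cn, value = TRUE)[1]
  if (is.na(xcol) || !xcol %in% cn)
    stop("covariate not found in the fitted model: ", covariate)
  x <- Z[, xcol]
  if (length(unique(x)) < 2) stop("covariate is constant")
  n <- length(x)
  x_order <- order(x, seq_len(n))   # stable order along the covariate axis

  beta <- fit$coefficients
  lp <- drop(Z %*% beta)
  w <- exp(lp)
  bh <- .breslow_cumhaz(time, status, lp)
  M <- status - bh$Lambda * w
  W_obs <- cumsum(M[x_order])
  stat <- max(abs(W_obs))

  if (resample == "simple") {
    M_ord <- M[x_order]
    sup_sim <- numeric(n_sim)
    block <- 500L
    done <- 0L
    while (done < n_sim) {
      b <- min(block, n_sim - done)
      G <- matrix(stats::rnorm(n * b), n, b)
      S <- apply(G * M_ord, 2, function(col) max(abs(cumsum(col))))
      sup_sim[(done + 1):(done + b)] <- S
      done <- done + b
    }
    return(list(statistic = stat, p = mean(sup_sim >= stat), n_sim = n_sim,
                resample = resample, x = x[x_order], W = W_obs))
  }

  # influence resampling: A[i, k] = subject i's compensated contribution
  # to W(x_k); columns follow the covariate order
  ev <- bh$event_times
  dl <- bh$dLambda
  ne <- length(ev)
  atrisk_w <- outer(ev, time, function(te, ti) as.numeric(ti >= te)) *
    rep(w, each = ne)                      # ne x n
  S0 <- rowSums(atrisk_w)
  # R1[e, k] = sum over subjects with X <= x_k at risk at event time e
  R1 <- t(apply(atrisk_w[, x_order, drop = FALSE], 1, cumsum))
  Ebar <- R1 / S0                           # ne x n (columns = cuts)
  # C[e, k] = cumulative over event times of Ebar * dLambda
  C <- apply(Ebar * dl, 2, cumsum)
  if (ne == 1) C <- matrix(C, nrow = 1)
  pos <- findInterval(time, ev)             # last event time <= t_i
  Cmat <- matrix(0, n, n)
  hasev <- pos > 0
  Cmat[hasev, ] <- C[pos[hasev], , drop = FALSE]
  # Ebar at the subject's own (event) time
  Eown <- matrix(0, n, n)
  ev_pos <- match(time, ev)
  has_own <- status > 0 & !is.na(ev_pos)
  Eown[has_own, ] <- Ebar[ev_pos[has_own], , drop = FALSE]

  step <- matrix(0, n, n)                   # step[i, k] = 1(X_i <= x_k)
  step[cbind(x_order, seq_len(n))] <- 1
  step <- t(apply(step, 1, cummax))
  A <- step * M - status * Eown + w * Cmat

  # propagate coefficient-estimation uncertainty: numeric derivative of
  # the cumulative process with respect to each coefficient
  p <- length(beta)
  H <- matrix(0, p, n)
  for (r in seq_len(p)) {
    epsr <- 1e-4 * max(1, abs(beta[r]))
    bp <- beta; bp[r] <- bp[r] + epsr
    bm <- beta; bm[r] <- bm[r] - epsr
    H[r, ] <- (.w_process(time, status, Z, bp, x_order) -
                 .w_process(time, status, Z, bm, x_order)) / (2 * epsr)
  }
  U <- stats::residuals(cox, type = "score")
  if (is.null(dim(U))) U <- matrix(U, ncol = 1)
  Iinv <- if (fit$robust && !is.null(cox$naive.var)) cox$naive.var else cox$var
  B <- U %*% Iinv %*% H                     # n x n correction term
  Atot <- A + B

  sup_sim <- numeric(n_sim)
  block <- 500L
  done <- 0L
  while (done < n_sim) {
    b <- min(block, n_sim - done)
    G <- matrix(stats::rnorm(n * b), n, b)
    S <- crossprod(G, Atot)                 # b x n simulated processes
    sup_sim[(done + 1):(done + b)] <- apply(abs(S), 1, max)
    done <- done + b
  }
  list(statistic = stat, p = mean(sup_sim >= stat), n_sim = n_sim,
       resample = resample, x = x[x_order], W = W_obs)
}
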