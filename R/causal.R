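#' Back-compute a log-scale SE from a ratio-scale confidence interval
#'
#' For a published hazard/odds ratio with a 95% CI, the log-scale SE is
#' \eqn{(\log u - \log l) / (2 \times 1.959964)}.
#'
#' @param estimate ratio-scale point estimate.
#' @param lower,upper 95% confidence limits on the ratio scale.
#' @return list with `estimate` (log scale) and `se`.
#' @examples
#' se_from_ci(1.27, 1.14, 1.41)$se   # 0.0542
#' @export
se_from_ci <- function(estimate, lower, upper) {
  if (any(c(estimate, lower, upper) <= 0))
    stop("ratio-scale estimate and CI bounds must be positive")
  if (lower > estimate || estimate > upper)
    stop("CI bounds must bracket the estimate")
  list(estimate = log(estimate),
       se = (log(upper) - log(lower)) / (2 * stats::qnorm(0.975)))
}

.new_causal_estimate <- function(estimate, se, method, stage1 = NULL,
                                 stage2 = NULL, extra = list()) {
  zq <- stats::qnorm(0.975)
  structure(c(list(
    estimate = estimate, se = se,
    lo = estimate - zq * se, hi = estimate + zq * se,
    hr = exp(estimate), hr_lo = exp(estimate - zq * se),
    hr_hi = exp(estimate + zq * se),
    p = 2 * stats::pnorm(-abs(estimate / se)),
    method = method, stage1 = stage1, stage2 = stage2
  ), extra), class = "causal_estimate")
}

#' @export
print.causal_estimate <- function(x, ...) {
  cat(sprintf("Causal hazard ratio per SD of log-resistin (%s):\n", x$method))
  cat(sprintf("  HR %.3f (95%% CI %.3f-%.3f), log-HR %.4f (SE %.4f), p = %.3g\n",
              x$hr, x$hr_lo, x$hr_hi, x$estimate, x$se, x$p))
  if (!is.null(x$weak_instrument) && isTRUE(x$weak_instrument))
    cat("  warning: weak instrument (stage-1 F below threshold)\n")
  invisible(x)
}

#' Wald-ratio causal estimate
#'
#' The causal log-HR per SD of the exposure is the ratio of the
#' instrument-outcome effect to the instrument-exposure effect:
#' \eqn{\beta_{IV} = b / a}. Its variance is propagated by the
#' first-order delta method, \eqn{var(b)/a^2 + b^2 var(a)/a^4}, treating
#' the two stages as uncorrelated (a documented approximation for the
#' one-sample setting).
#'
#' @param stage1_estimate,stage1_se per-allele effect on the
#'   standardized exposure and its SE.
#' @param stage2_estimate,stage2_se per-allele log-HR and its SE.
#' @param tol stage-1 effects with `|a| < tol` raise a weak-instrument
#'   error.
#' @return A `causal_estimate` (method `"wald_ratio"`).
#' @examples
#' wald_ratio(0.5, 0, log(1.2), 0.1)$hr   # 1.44
#' @export
wald_ratio <- function(stage1_estimate, stage1_se,
                       stage2_estimate, stage2_se, tol = 1e-8) {
  a <- stage1_estimate; b <- stage2_estimate
  if (!is.finite(a) || abs(a) < tol)
    stop("weak instrument: stage-1 effect within tolerance of zero")
  est <- b / a
  v <- stage2_se^2 / a^2 + b^2 * stage1_se^2 / a^4
  .new_causal_estimate(est, sqrt(v), "wald_ratio",
                       stage1 = list(estimate = a, se = stage1_se),
                       stage2 = list(estimate = b, se = stage2_se))
}

#' Two-stage predictor-substitution causal Cox estimate
#'
#' Stage 1 regresses standardized log-resistin on the risk-score allele
#' count (plus covariates and cohort indicators); stage 2 fits a Cox
#' model of mortality on the stage-1 fitted exposure with the same
#' covariates. The coefficient of the fitted exposure is the causal
#' log-HR per SD of log-resistin. The default SE is the robust sandwich
#' from stage 2 (which ignores stage-1 estimation error); a nonparametric
#' subject-resampling bootstrap is available.
#'
#' Subjects with incomplete genotypes are excluded (complete-case
#' instrument policy). The stage-1 partial F statistic of the instrument
#' is attached; values below `f_threshold` flag (but do not fail) the
#' estimate as weak-instrument.
#'
#' @param table cohort data.frame.
#' @param grs a [build_grs()] profile on the same rows.
#' @param covariates adjustment columns used in both stages.
#' @param boot number of bootstrap replicates for the SE (0 = sandwich
#'   SE only).
#' @param f_threshold report-only weak-instrument threshold (default 10).
#' @param seed optional seed for the bootstrap.
#' @return A `causal_estimate` (method `"two_stage"`) with `stage1_f`
#'   and `weak_instrument` fields.
#' @export
two_stage_cox <- function(table, grs, covariates = character(0), boot = 0,
                          f_threshold = 10, seed = NULL) {
  keep <- !is.na(grs$score) & !is.na(table$resistin)
  tab <- table[keep, , drop = FALSE]
  score <- grs$score[keep]
  if (length(unique(score)) < 2)
    stop("weak instrument: risk score is constant among complete cases")

  fit_once <- function(tab, score) {
    z <- standardize_resistin(tab$resistin)
    df1 <- .analysis_frame(tab, as.numeric(z), covariates = covariates)
    df1$score <- score
    s1 <- stats::lm(.y ~ ., data = df1)
    # partial F for the instrument
    s0 <- stats::update(s1, . ~ . - score)
    an <- stats::anova(s0, s1)
    f_stat <- an[2, "F"]
    a <- stats::coef(s1)[["score"]]
    a_se <- sqrt(stats::vcov(s1)["score", "score"])
    fitted_z <- stats::fitted(s1)
    s2 <- fit_cox(tab, fitted_z, covariates = covariates, robust = TRUE)
    est <- s2$coefficients[[".x"]]
    se <- sqrt(s2$vcov_robust[".x", ".x"])
    list(est = est, se = se, a = a, a_se = a_se, f = f_stat, s2 = s2)
  }

  base <- fit_once(tab, score)
  se <- base$se
  boot_se <- NULL
  if (boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    n <- nrow(tab)
    bs <- vapply(seq_len(boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(fit_once(tab[idx, , drop = FALSE], score[idx])$est,
               error = function(e) NA_real_)
    }, numeric(1))
    boot_se <- stats::sd(bs, na.rm = TRUE)
    se <- boot_se
  }
  .new_causal_estimate(
    base$est, se, "two_stage",
    stage1 = list(estimate = base$a, se = base$a_se, f = base$f),
    stage2 = list(estimate = base$est, se = base$se),
    extra = list(stage1_f = base$f,
                 weak_instrument = is.finite(base$f) && base$f < f_threshold,
                 boot_se = boot_se, n = nrow(tab),
                 events = base$s2$events)
  )
}

#' Cochran Q comparison of the causal and observational estimates
#'
#' \eqn{Q = (\theta_c - \theta_o)^2 / (SE_c^2 + SE_o^2)} with a
#' chi-square (1 df) p-value; the two estimates are treated as
#' independent.
#'
#' @param causal_estimate,causal_se causal log-HR and SE.
#' @param observed_estimate,observed_se observational log-HR and SE.
#' @return list with `Q`, `df`, `p`.
#' @examples
#' ca <- se_from_ci(2.17, 1.22, 3.87)
#' ob <- se_from_ci(1.27, 1.14, 1.41)
#' causal_vs_observed_q(ca$estimate, ca$se, ob$estimate, ob$se)$p  # 0.074
#' @export
causal_vs_observed_q <- function(causal_estimate, causal_se,
                                 observed_estimate, observed_se) {
  if (causal_estimate == observed_estimate)
    return(list(Q = 0, df = 1L, p = 1))
  if (causal_se <= 0 || observed_se <= 0)
    stop("zero or negative SE with differing estimates")
  Q <- (causal_estimate - observed_estimate)^2 / (causal_se^2 + observed_se^2)
  list(Q = Q, df = 1L, p = stats::pchisq(Q, 1, lower.tail = FALSE))
}
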