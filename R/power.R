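#' Required number of events (Schoenfeld relation)
#'
#' Smallest integer number of events D satisfying
#' \eqn{D = (z_{1-\alpha/2} + z_{power})^2 / (\beta^2 \sigma_x^2)} for a
#' Cox model with effect \eqn{\beta} (log-HR per unit of the predictor)
#' and predictor variance \eqn{\sigma_x^2}.
#'
#' @param alpha two-sided type I error.
#' @param power target power.
#' @param log_hr log hazard ratio per unit of the predictor.
#' @param var_x predictor variance.
#' @return Required events (integer).
#' @examples
#' schoenfeld_events(0.05, 0.80, log(2), 1)      # 17
#' schoenfeld_events(0.05, 0.80, log(1.15), 1)   # 402
#' @export
schoenfeld_events <- function(alpha, power, log_hr, var_x) {
  .check_alpha_power(alpha, power)
  if (log_hr == 0) stop("log_hr must be nonzero")
  if (var_x <= 0) stop("var_x must be positive")
  zsum <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  ceiling(zsum^2 / (log_hr^2 * var_x))
}

#' Minimal detectable hazard ratio at a given number of events
#'
#' Inverts the Schoenfeld relation:
#' \eqn{HR = \exp\sqrt{(z_{1-\alpha/2} + z_{power})^2 / (D \sigma_x^2)}}.
#'
#' @param events observed/expected number of events D.
#' @inheritParams schoenfeld_events
#' @return The minimal detectable HR (> 1).
#' @examples
#' detectable_hr(403, 0.05, 0.80, 1)       # 1.15
#' detectable_hr(403, 0.05, 0.80, 0.6245)  # 1.19
#' @export
detectable_hr <- function(events, alpha, power, var_x) {
  .check_alpha_power(alpha, power)
  if (events < 1) stop("events must be at least 1")
  if (var_x <= 0) stop("var_x must be positive")
  zsum <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  exp(sqrt(zsum^2 / (events * var_x)))
}

#' Minimal detectable linear regression slope
#'
#' \eqn{(z_{1-\alpha/2} + z_{power}) \sigma_{res} / \sqrt{n \sigma_x^2}}
#' — the slope detectable with the stated power in a simple linear
#' regression with predictor variance \eqn{\sigma_x^2} and residual SD
#' \eqn{\sigma_{res}}.
#'
#' @param n sample size (at least 3).
#' @inheritParams schoenfeld_events
#' @param residual_sd residual SD of the outcome.
#' @return The minimal detectable slope.
#' @examples
#' detectable_slope(1479, 0.05, 0.80, 0.6245, 1)  # 0.092
#' @export
detectable_slope <- function(n, alpha, power, var_x, residual_sd = 1) {
  .check_alpha_power(alpha, power)
  if (n < 3) stop("n must be at least 3")
  if (var_x <= 0) stop("var_x must be positive")
  if (residual_sd <= 0) stop("residual_sd must be positive")
  zsum <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  zsum * residual_sd / sqrt(n * var_x)
}

.check_alpha_power <- function(alpha, power) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (power <= 0 || power >= 1) stop("power must lie in (0, 1)")
}

# administrative censoring horizon times baseline rate solved so the
# expected number of events matches the target, for a log-normal-free
# design with standard-normal predictor and log-linear hazard
.solve_rate_for_events <- function(n, log_hr, horizon, target_events) {
  p_target <- target_events / n
  if (p_target <= 0 || p_target >= 1)
    stop("target_events must lie strictly between 0 and n")
  p_event <- function(lambda0) {
    f <- function(z) stats::dnorm(z) * (1 - exp(-lambda0 * exp(log_hr * z) * horizon))
    stats::integrate(f, -8, 8)$value
  }
  stats::uniroot(function(l) p_event(l) - p_target,
                 lower = 1e-8, upper = 100, tol = 1e-10)$root
}

#' Power specification
#'
#' Bundles the parameters of an analytic or simulation power run.
#'
#' @param alpha two-sided type I error.
#' @param power target power (used by the analytic helpers).
#' @param n sample size.
#' @param target_events expected number of events (censoring is
#'   calibrated to reach it in the survival design).
#' @param effect effect size: log-HR per predictor unit (survival) or
#'   regression slope (linear).
#' @param var_x predictor variance.
#' @param residual_sd residual SD for the linear design.
#' @param horizon administrative censoring horizon, years (survival).
#' @param replicates number of Monte-Carlo replicates.
#' @param seed integer seed.
#' @return A `power_spec` list.
#' @export
power_spec <- function(alpha = 0.05, power = 0.80, n = 1479,
                       target_events = 403, effect = log(1.15), var_x = 1,
                       residual_sd = 1, horizon = 10, replicates = 1000,
                       seed = 1L) {
  .check_alpha_power(alpha, power)
  if (n < 2) stop("n must be at least 2")
  if (var_x <= 0) stop("var_x must be positive")
  if (replicates < 100) stop("replicates must be at least 100")
  structure(list(alpha = alpha, power = power, n = n,
                 target_events = target_events, effect = effect,
                 var_x = var_x, residual_sd = residual_sd,
                 horizon = horizon, replicates = replicates,
                 seed = as.integer(seed)), class = "power_spec")
}

#' Empirical power by simulation
#'
#' Survival design: per replicate, a standard-normal predictor (scaled
#' to `var_x`) with exponential event times under
#' log-hazard = baseline + effect x predictor, administrative censoring
#' calibrated so the expected number of events matches
#' `target_events`; a univariate Cox model is fitted and the two-sided
#' Wald p-value compared with `alpha`. Linear design: Gaussian outcome
#' `effect x predictor + noise`, slope t-test.
#'
#' @param spec a [power_spec()].
#' @param design `"cox"` or `"linear"`.
#' @return list with `power` (fraction rejecting), `mc_se` (binomial
#'   Monte-Carlo SE), `mean_events` (survival design), `replicates`,
#'   and `analytic` (the Schoenfeld/normal-approximation power at the
#'   same settings).
#' @export
simulate_power <- function(spec, design = c("cox", "linear")) {
  design <- match.arg(design)
  set.seed(spec$seed)
  n <- spec$n
  zq <- stats::qnorm(1 - spec$alpha / 2)

  if (design == "cox") {
    lambda0 <- .solve_rate_for_events(n, spec$effect * sqrt(spec$var_x),
                                      spec$horizon, spec$target_events)
    rej <- logical(spec$replicates)
    nev <- numeric(spec$replicates)
    for (r in seq_len(spec$replicates)) {
      x <- stats::rnorm(n, 0, sqrt(spec$var_x))
      tt <- stats::rexp(n) / (lambda0 * exp(spec$effect * x))
      status <- as.numeric(tt <= spec$horizon)
      obs <- pmin(tt, spec$horizon)
      fit <- survival::coxph(survival::Surv(obs, status) ~ x)
      zstat <- stats::coef(fit)[1] / sqrt(fit$var[1, 1])
      rej[r] <- abs(zstat) > zq
      nev[r] <- sum(status)
    }
    d_expected <- spec$target_events
    analytic <- stats::pnorm(abs(spec$effect) * sqrt(d_expected * spec$var_x) - zq)
    out <- list(power = mean(rej),
                mc_se = sqrt(mean(rej) * (1 - mean(rej)) / spec$replicates),
                mean_events = mean(nev), replicates = spec$replicates,
                analytic = analytic, design = design)
  } else {
    rej <- logical(spec$replicates)
    for (r in seq_len(spec$replicates)) {
      x <- stats::rnorm(n, 0, sqrt(spec$var_x))
      y <- spec$effect * x + stats::rnorm(n, 0, spec$residual_sd)
      p <- summary(stats::lm(y ~ x))$coefficients["x", "Pr(>|t|)"]
      rej[r] <- p < spec$alpha
    }
    analytic <- stats::pnorm(abs(spec$effect) * sqrt(n * spec$var_x) /
                               spec$residual_sd - zq)
    out <- list(power = mean(rej),
                mc_se = sqrt(mean(rej) * (1 - mean(rej)) / spec$replicates),
                mean_events = NA_real_, replicates = spec$replicates,
                analytic = analytic, design = design)
  }
  out
}
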