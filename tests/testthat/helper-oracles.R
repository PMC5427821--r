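# Independent oracles and fixture builders used across the suite.

# Brute-force Cox oracle: log partial likelihood on a dense grid.
# Valid for untied event times (where Efron and Breslow coincide).
brute_force_cox <- function(time, status, x, lower = -3, upper = 3,
                            step = 1e-4) {
  stopifnot(!anyDuplicated(time[status == 1]))
  beta <- seq(lower, upper, by = step)
  ll <- numeric(length(beta))
  for (i in which(status == 1)) {
    at_risk <- time >= time[i]
    ll <- ll + beta * x[i] -
      log(colSums(exp(outer(x[at_risk], beta))))
  }
  beta[which.max(ll)]
}

# small survival dataset with exponential times and uniform censoring
make_surv_data <- function(n, beta = 0.3, rate = 0.05, cmin = 4, cmax = 12,
                           cohort = "A") {
  x <- rnorm(n)
  tt <- rexp(n) / (rate * exp(beta * x))
  cens <- runif(n, cmin, cmax)
  data.frame(x = x, follow_up = pmin(tt, cens), event = tt <= cens,
             cohort = cohort)
}

# single small synthetic cohort configuration, for fast simulations
small_config <- function(n = 400, ...) {
  co <- default_cohort_specs()[1, , drop = FALSE]
  co$n <- as.integer(n)
  sim_config(cohorts = co, ...)
}

# cohort table whose per-score counts match a requested distribution
table_with_scores <- function(counts) {
  # counts named by score 0..4; realize each score with a fixed (g1, g2)
  combos <- list(`0` = c(0, 0), `1` = c(0, 1), `2` = c(1, 1),
                 `3` = c(1, 2), `4` = c(2, 2))
  g <- do.call(rbind, lapply(names(counts), function(s) {
    k <- counts[[s]]
    if (k == 0) return(NULL)
    matrix(rep(combos[[s]], k), ncol = 2, byrow = TRUE)
  }))
  data.frame(g1 = g[, 1], g2 = g[, 2])
}
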