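test_that("fit_cox matches the hand-coded partial likelihood on tiny data", {
  # fixed six-subject dataset, untied times
  d <- data.frame(follow_up = c(1.1, 2.3, 3.7, 4.1, 5.9, 7.3),
                  event = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE),
                  x = c(0.5, -1.2, 0.3, 1.7, -0.4, 0.9),
                  cohort = "A")
  fit <- fit_cox(d, "x")
  oracle <- brute_force_cox(d$follow_up, d$event, d$x)
  expect_lt(abs(fit$coefficients[[".x"]] - oracle), 1e-4 + 1e-4)

  set.seed(23)
  for (i in 1:3) {
    d <- make_surv_data(8, beta = 0.5, rate = 0.12)
    fit <- fit_cox(d, "x")
    oracle <- brute_force_cox(d$follow_up, d$event, d$x)
    expect_lt(abs(fit$coefficients[[".x"]] - oracle), 2e-4)
  }
})

test_that("two-group exponential data recover the true rate ratio", {
  set.seed(24)
  covered <- logical(50)
  for (r in 1:50) {
    n <- 300
    grp <- rep(0:1, each = n / 2)
    tt <- rexp(n, rate = 0.05 * 2^grp)
    cens <- runif(n, 5, 15)
    d <- data.frame(follow_up = pmin(tt, cens), event = tt <= cens,
                    cohort = "A")
    fit <- fit_cox(d, grp)
    est <- fit$coefficients[[".x"]]
    se <- sqrt(fit$vcov[".x", ".x"])
    covered[r] <- est - 1.96 * se <= log(2) && log(2) <= est + 1.96 * se
  }
  expect_gte(mean(covered), 0.86)
})

test_that("a randomly permuted exposure gives a level-alpha test", {
  set.seed(25)
  rej <- replicate(200, {
    d <- make_surv_data(150, beta = 0.4)
    d$x <- sample(d$x)
    fit <- fit_cox(d, "x")
    z <- fit$coefficients[[".x"]] / sqrt(fit$vcov[".x", ".x"])
    abs(z) > 1.959964
  })
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / 200) + 0.01)
})

test_that("fit_cox rejects invalid inputs", {
  d <- make_surv_data(20)
  d$event <- FALSE
  expect_error(fit_cox(d, "x"), "no events")
  d2 <- make_surv_data(20)
  d2$follow_up[3] <- Inf
  expect_error(fit_cox(d2, "x"), "non-finite")
})

test_that("Cochran Q reproduces closed-form identities", {
  expect_equal(heterogeneity_q(c(0.3, 0.3), c(0.1, 0.2)),
               list(Q = 0, df = 1L, p = 1))
  # difference of exactly 1.959964 * sqrt(se1^2 + se2^2) gives p = 0.05
  se <- c(0.08, 0.11)
  delta <- stats::qnorm(0.975) * sqrt(sum(se^2))
  h <- heterogeneity_q(c(0.2, 0.2 + delta), se)
  expect_equal(h$p, 0.05, tolerance = 1e-10)
  expect_error(heterogeneity_q(c(0.1, 0.2), c(0, 0.1)), "SE")
  expect_error(heterogeneity_q(0.1, 0.1), "at least 2")
})

test_that("heterogeneity and pooling agree with metafor on random inputs", {
  skip_if_not_installed("metafor")
  set.seed(26)
  for (i in 1:10) {
    k <- sample(3:6, 1)
    est <- rnorm(k, 0.3, 0.15)
    se <- runif(k, 0.05, 0.2)
    mine_q <- heterogeneity_q(est, se)
    mine_p <- pool_fixed_effect(est, se)
    ref <- metafor::rma(yi = est, sei = se, method = "FE")
    expect_equal(mine_q$Q, as.numeric(ref$QE), tolerance = 1e-8)
    expect_equal(mine_q$p, as.numeric(ref$QEp), tolerance = 1e-8)
    expect_equal(mine_p$estimate, as.numeric(ref$beta), tolerance = 1e-8)
    expect_equal(mine_p$se, as.numeric(ref$se), tolerance = 1e-8)
  }
})

test_that("pooling identities hold on constructed inputs", {
  one <- pool_fixed_effect(0.25, 0.1)
  expect_equal(one$estimate, 0.25)
  expect_equal(one$se, 0.1)
  two <- pool_fixed_effect(c(0.25, 0.25), c(0.1, 0.1))
  expect_equal(two$estimate, 0.25)
  expect_equal(two$se, 0.1 / sqrt(2), tolerance = 1e-12)
  expect_error(pool_fixed_effect(numeric(0), numeric(0)), "no estimates")
})

test_that("incidence rates match printed events over person-years", {
  expect_equal(round(incidence_rate(78, 1890), 1), 4.1)
  expect_equal(round(incidence_rate(206, 7504), 1), 2.7)
  expect_equal(round(incidence_rate(119, 3060), 1), 3.9)
  expect_equal(incidence_rate(0, 100), 0)
  expect_error(incidence_rate(5, 0), "positive")
})

test_that("model suite attenuates under confounding and validates columns", {
  cfg <- sim_config()
  m1 <- m3 <- numeric(6)
  for (r in 1:6) {
    d <- simulate_multi_cohort(cfg, seed = 600 + r)
    z <- standardize_resistin(d$resistin)
    ms <- model_suite(d, as.numeric(z))
    m1[r] <- ms$estimate[ms$model == "1" & ms$cohort == "combined"]
    m3[r] <- ms$estimate[ms$model == "3" & ms$cohort == "combined"]
  }
  # confounders inflate the unadjusted estimate on average
  expect_gt(mean(m1), mean(m3))

  d <- simulate_multi_cohort(cfg, seed = 601)
  d$bmi <- NULL
  expect_error(model_suite(d, rnorm(nrow(d))), "bmi")
})

test_that("robust CIs trigger at about the threshold rate under homogeneity", {
  set.seed(27)
  frac <- replicate(100, {
    d <- do.call(rbind, lapply(c("A", "B", "C"), function(co)
      make_surv_data(120, beta = 0.3, cohort = co)))
    ms <- model_suite(d, "x", models = "1")
    any(ms$robust[ms$cohort == "combined"])
  })
  # heterogeneity p < 0.10 should fire ~10% of the time under the null
  expect_lt(abs(mean(frac) - 0.10), 3 * sqrt(0.1 * 0.9 / 100) + 0.01)
})

test_that("robust and model-based standard errors converge when correctly specified", {
  set.seed(28)
  d <- make_surv_data(4000, beta = 0.4)
  fit <- fit_cox(d, "x", robust = TRUE)
  r <- sqrt(fit$vcov_robust[".x", ".x"]) / sqrt(fit$vcov[".x", ".x"])
  expect_lt(abs(r - 1), 0.1)
})

test_that("supremum statistic depends only on the covariate ordering", {
  set.seed(29)
  d <- make_surv_data(200, beta = 0.3)
  fit <- fit_cox(d, "x")
  st <- supremum_linearity_test(fit, ".x", n_sim = 200, seed = 1)

  # the observed statistic is the sup of cumulative residuals along the
  # covariate order, so any strictly monotone relabeling (here exp)
  # leaves it unchanged
  lp <- drop(fit$coxph_fit$x %*% fit$coefficients)
  bh <- resistinMR:::.breslow_cumhaz(fit$data$.time, fit$data$.status, lp)
  M <- fit$data$.status - bh$Lambda * exp(lp)
  expect_equal(st$statistic,
               max(abs(cumsum(M[order(exp(fit$data$.x))]))),
               tolerance = 1e-10)

  expect_error(supremum_linearity_test(fit, ".x", n_sim = 50), "n_sim")
})

test_that("supremum test does not reject on default study-like data", {
  cfg <- sim_config()
  d <- simulate_multi_cohort(cfg, seed = 911)
  z <- standardize_resistin(d$resistin)
  fit <- fit_cox(d, as.numeric(z))
  st <- supremum_linearity_test(fit, ".x", n_sim = 1000, seed = 2)
  expect_gt(st$p, 0.05)
  expect_true(st$statistic > 0)
})
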