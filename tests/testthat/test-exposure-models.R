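test_that("standardization divides logged values by their SD", {
  z <- standardize_resistin(exp(1:3))
  expect_equal(as.numeric(z), c(1, 2, 3), tolerance = 1e-12)
  expect_equal(attr(z, "sd"), 1)

  set.seed(3)
  v <- exp(rnorm(200, 2, 0.6))
  expect_equal(stats::sd(standardize_resistin(v)), 1, tolerance = 1e-12)
  zc <- standardize_resistin(v, center = TRUE)
  expect_equal(mean(zc), 0, tolerance = 1e-12)

  expect_error(standardize_resistin(c(1, 0, 2)), "positive")
})

test_that("exposure model recovers a known per-allele effect", {
  set.seed(14)
  cfg <- small_config(n = 500)
  covered <- logical(60)
  for (r in seq_len(60)) {
    d <- simulate_multi_cohort(cfg, seed = 300 + r)
    g <- build_grs(d)
    fit <- fit_exposure_model(d, g, "continuous")
    est <- fit$coefficients[["grs"]]
    se <- sqrt(fit$vcov["grs", "grs"])
    # per-allele truth on the standardized scale: the generator's common
    # allele effect divided by the sample SD of log-resistin
    truth_r <- cfg$allele_effects[1] / attr(standardize_resistin(d$resistin), "sd")
    covered[r] <- est - 1.96 * se <= truth_r && truth_r <= est + 1.96 * se
  }
  expect_gte(mean(covered), 0.85)
})

test_that("overall exposure p-value is level under a null genetic effect", {
  cfg <- small_config(n = 300, allele_effects = c(0, 0))
  set.seed(15)
  pv <- replicate(150, {
    d <- simulate_multi_cohort(cfg, seed = sample.int(1e6, 1))
    g <- build_grs(d)
    fit_exposure_model(d, g, "categorical")$overall_p
  })
  expect_lt(abs(mean(pv < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 150) + 0.01)
})

test_that("degenerate designs are rejected", {
  d <- data.frame(g1 = rep(1L, 30), g2 = rep(1L, 30),
                  resistin = exp(rnorm(30)), cohort = "A")
  g <- build_grs(d)
  expect_error(fit_exposure_model(d, g, "continuous"), "distinct")
})

test_that("AIC difference equals the LR statistic minus twice the df gap", {
  set.seed(16)
  d <- simulate_multi_cohort(small_config(n = 400), seed = 90)
  g <- build_grs(d)
  fit_cat <- fit_exposure_model(d, g, "categorical")
  fit_cont <- fit_exposure_model(d, g, "continuous")
  lr <- 2 * (stats::logLik(fit_cat$lm_fit) - stats::logLik(fit_cont$lm_fit))
  dk <- attr(stats::logLik(fit_cat$lm_fit), "df") -
    attr(stats::logLik(fit_cont$lm_fit), "df")
  expect_equal(fit_cont$aic - fit_cat$aic, as.numeric(lr) - 2 * dk,
               tolerance = 1e-8)
})

test_that("AIC coding selection tracks the true dose-response shape", {
  # linear truth: continuous coding should usually win
  set.seed(17)
  pick <- function(cfg, seeds) vapply(seeds, function(s) {
    d <- simulate_multi_cohort(cfg, seed = s)
    g <- build_grs(d)
    attr(compare_codings(fit_exposure_model(d, g, "categorical"),
                         fit_exposure_model(d, g, "continuous")), "chosen")
  }, character(1))
  lin <- pick(small_config(n = 800), 400 + 1:15)
  expect_gt(mean(lin == "continuous"), 0.5)

  # step truth: a strong jump at 3+ should favour the categorical coding
  stp <- pick(small_config(n = 800, allele_effects = c(0.02, 0.02),
                           score_jump = 0.5), 500 + 1:15)
  expect_gt(mean(stp == "categorical"), 0.5)
})

test_that("coding selection validates inputs and breaks ties to continuous", {
  set.seed(18)
  d <- simulate_multi_cohort(small_config(n = 300), seed = 71)
  g <- build_grs(d)
  fc <- fit_exposure_model(d, g, "categorical")
  ft <- fit_exposure_model(d, g, "continuous")
  expect_error(compare_codings(ft, fc), "categorical and a continuous")
  ft2 <- ft; ft2$n <- ft$n - 1L
  expect_error(compare_codings(fc, ft2), "different numbers of rows")
  # exact AIC tie goes to the continuous (fewer-parameter) coding
  ft3 <- ft; ft3$aic <- fc$aic
  expect_equal(attr(compare_codings(fc, ft3), "chosen"), "continuous")
})

test_that("percent change is exact ratio arithmetic with delta-method SE", {
  fit <- structure(list(
    coding = "categorical",
    coefficients = c("(Intercept)" = 2, "grs1" = 0, "grs2" = 0.5),
    vcov = matrix(0, 3, 3,
                  dimnames = list(c("(Intercept)", "grs1", "grs2"),
                                  c("(Intercept)", "grs1", "grs2")))
  ), class = "exposure_fit")
  pc <- percent_change_means(fit)
  expect_equal(pc$percent, c(0, 0, 25))
  expect_equal(pc$se, c(0, 0, 0))

  fit$coefficients[["(Intercept)"]] <- 1e-9
  expect_error(percent_change_means(fit), "tolerance")
})

test_that("slopes on the standardized scale equal raw-log slopes over the SD", {
  set.seed(19)
  d <- simulate_multi_cohort(small_config(n = 500), seed = 44)
  g <- build_grs(d)
  z <- standardize_resistin(d$resistin)
  fit_std <- fit_exposure_model(d, g, "continuous", response = z)
  raw <- log(d$resistin)
  fit_raw <- stats::lm(raw ~ g$score)
  expect_equal(fit_std$coefficients[["grs"]],
               stats::coef(fit_raw)[[2]] / attr(z, "sd"),
               tolerance = 1e-10)
})
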