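test_that("genotype simulation follows Hardy-Weinberg sampling", {
  expect_identical(simulate_genotypes(1000, 0, seed = 1), rep(0L, 1000))
  expect_error(simulate_genotypes(10, 1.2), "maf")
  expect_error(simulate_genotypes(0, 0.5), "n")

  g <- simulate_genotypes(1e5, 0.5, seed = 11)
  props <- tabulate(g + 1L, 3) / 1e5
  mc_se <- sqrt(c(0.25, 0.5, 0.25) * c(0.75, 0.5, 0.75) / 1e5)
  expect_true(all(abs(props - c(0.25, 0.5, 0.25)) < 3 * mc_se))
})

test_that("hwe_test rejects at about the nominal rate on HWE genotypes", {
  set.seed(21)
  rej <- replicate(1000, {
    g <- stats::rbinom(500, 2, 0.3)
    ct <- genotype_counts(g)
    hwe_test(ct[1], ct[2], ct[3])$p < 0.05
  })
  # binomial 3-SE band around 5%
  expect_gt(mean(rej), 0.05 - 3 * sqrt(0.05 * 0.95 / 1000))
  expect_lt(mean(rej), 0.05 + 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 5)
  d1 <- simulate_multi_cohort(cfg)
  d2 <- simulate_multi_cohort(cfg)
  expect_identical(d1, d2)

  # a single-cohort run reproduces the corresponding cohort generator
  co <- default_cohort_specs()[2, , drop = FALSE]
  cfg1 <- sim_config(cohorts = co, seed = 9)
  expect_identical(simulate_multi_cohort(cfg1), simulate_cohort(cfg1, "GMS"))
})

test_that("multi-cohort output has the study dimensions and labels", {
  d <- simulate_multi_cohort(sim_config(seed = 2))
  expect_equal(nrow(d), 1479)
  expect_equal(as.numeric(table(d$cohort)[c("GHS", "GMS", "FMS")]),
               c(350, 698, 431))
  expect_true(all(d$follow_up >= 0))
  expect_true(all(d$resistin > 0))
  expect_true(all(d$g1 %in% 0:2) && all(d$g2 %in% 0:2))
})

test_that("config validation rejects degenerate inputs", {
  expect_error(sim_config(maf1 = -0.1), "frequencies")
  co <- default_cohort_specs()
  co$label[2] <- "GHS"
  expect_error(sim_config(cohorts = co), "duplicate")
  co2 <- default_cohort_specs()
  co2$ir_target[1] <- 0
  expect_error(sim_config(cohorts = co2), "positive")
  expect_error(simulate_cohort(sim_config(), "NOPE"), "unknown cohort")
})

test_that("generator hits the study calibration targets on average", {
  cfg <- sim_config()
  reps <- 25
  irs <- matrix(NA_real_, reps, 3)
  py <- ev <- numeric(reps)
  res_mean <- matrix(NA_real_, reps, 3)
  for (r in seq_len(reps)) {
    d <- simulate_multi_cohort(cfg, seed = 100 + r)
    dd <- cohort_descriptives(d)
    irs[r, ] <- dd$incidence_rate[match(c("GHS", "GMS", "FMS"), dd$cohort)]
    res_mean[r, ] <- dd$resistin_mean[match(c("GHS", "GMS", "FMS"), dd$cohort)]
    py[r] <- dd$person_years[dd$cohort == "combined"]
    ev[r] <- dd$events[dd$cohort == "combined"]
  }
  expect_true(all(abs(colMeans(irs) - c(4.13, 2.75, 3.89)) < 0.35))
  expect_lt(abs(mean(py) - 12454) / 12454, 0.03)
  expect_lt(abs(mean(ev) - 403) / 403, 0.10)
  expect_true(all(abs(colMeans(res_mean) - c(10.7, 10.1, 8.5)) < 0.5))
})

test_that("a null configuration yields a null genetic association", {
  cfg <- small_config(n = 400, causal_loghr_per_sd = 0,
                      allele_effects = c(0, 0))
  set.seed(33)
  pvals <- replicate(100, {
    d <- simulate_multi_cohort(cfg, seed = sample.int(1e6, 1))
    g <- build_grs(d)
    fit <- fit_cox(d, as.numeric(g$score))
    eff <- fit$coefficients[[".x"]] / sqrt(fit$vcov[".x", ".x"])
    2 * stats::pnorm(-abs(eff))
  })
  expect_lt(mean(pvals < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 100))
})

test_that("stronger causal effects produce more events at a fixed baseline", {
  # with rate calibration off, the baseline hazard is held fixed, so a
  # stronger causal effect must raise the expected event count
  cfg0 <- small_config(n = 2000, causal_loghr_per_sd = 0,
                       calibrate_rates = FALSE)
  cfg1 <- small_config(n = 2000, causal_loghr_per_sd = 1.0,
                       calibrate_rates = FALSE)
  ev <- function(cfg) mean(vapply(1:8, function(r)
    sum(simulate_multi_cohort(cfg, seed = 50 + r)$event), numeric(1)))
  expect_gt(ev(cfg1), ev(cfg0))
})

test_that("missing-genotype fraction drives the exclusion policy", {
  cfg <- small_config(n = 1000, missing_geno_frac = 0.05)
  d <- simulate_multi_cohort(cfg, seed = 77)
  expect_gt(sum(is.na(d$g1)), 0)
  g <- build_grs(d)
  expect_equal(g$n_genotyped + g$n_excluded, nrow(d))
  expect_equal(sum(g$category_counts), g$n_genotyped)
})
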