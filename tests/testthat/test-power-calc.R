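test_that("Schoenfeld event counts match the closed form", {
  expect_equal(schoenfeld_events(0.05, 0.80, log(2), 1), 17)
  expect_equal(schoenfeld_events(0.05, 0.80, log(1.15), 1), 402)
  # power 0.5: z_power = 0, so D = z_{1-a/2}^2 / (b^2 s^2)
  expect_equal(schoenfeld_events(0.05, 0.5, 0.3, 1),
               ceiling(stats::qnorm(0.975)^2 / 0.09))
  expect_error(schoenfeld_events(0.05, 0.8, 0, 1), "nonzero")
})

test_that("detectable hazard ratios reproduce the study's power statement", {
  expect_equal(round(detectable_hr(403, 0.05, 0.80, 1), 2), 1.15)
  # risk-score variance from the printed category counts 231/587/599/60/2
  counts <- c(231, 587, 599, 60, 2)
  s <- rep(0:4, counts)
  expect_equal(round(stats::var(s), 3), 0.624, tolerance = 1e-3)
  expect_equal(round(detectable_hr(403, 0.05, 0.80, stats::var(s)), 2), 1.19)

  # monotone limit: more events, smaller detectable HR, tending to 1
  hrs <- vapply(c(100, 1000, 10000, 1e6), detectable_hr,
                numeric(1), alpha = 0.05, power = 0.8, var_x = 1)
  expect_true(all(diff(hrs) < 0))
  expect_lt(hrs[4] - 1, 0.01)
  expect_error(detectable_hr(403, 0.05, 0.8, 0), "var_x")
})

test_that("events and detectable HR are inverse up to the integer ceiling", {
  for (hr in c(1.1, 1.3, 1.8)) {
    d <- schoenfeld_events(0.05, 0.80, log(hr), 1)
    expect_lte(detectable_hr(d, 0.05, 0.80, 1), hr + 1e-10)
    expect_gt(detectable_hr(d - 1, 0.05, 0.80, 1), hr)
  }
})

test_that("detectable slope follows the linear-power closed form", {
  sl <- detectable_slope(1479, 0.05, 0.80, 0.6245, 1)
  expect_equal(sl, 0.0922, tolerance = 1e-3)
  # linear in the residual SD
  expect_equal(detectable_slope(1479, 0.05, 0.80, 0.6245, 2), 2 * sl,
               tolerance = 1e-12)
  # round trip: n chosen for a slope returns that slope at var_x = 1
  zsum <- stats::qnorm(0.975) + stats::qnorm(0.80)
  n <- zsum^2 / 0.2^2
  expect_equal(detectable_slope(n, 0.05, 0.80, 1, 1), 0.2, tolerance = 1e-10)
})

test_that("simulated power is level under the null and rises with events", {
  null_spec <- power_spec(n = 400, target_events = 150, effect = 0,
                          replicates = 400, horizon = 10, seed = 31)
  null_run <- simulate_power(null_spec)
  expect_lt(abs(null_run$power - 0.05), 3 * sqrt(0.05 * 0.95 / 400) + 0.01)

  lo <- simulate_power(power_spec(n = 400, target_events = 100,
                                  effect = log(1.4), replicates = 300,
                                  seed = 32))
  hi <- simulate_power(power_spec(n = 400, target_events = 200,
                                  effect = log(1.4), replicates = 300,
                                  seed = 33))
  tol <- 2 * sqrt(lo$mc_se^2 + hi$mc_se^2)
  expect_gt(hi$power, lo$power - tol)
  # censoring calibration delivers the requested expected event count
  expect_lt(abs(lo$mean_events - 100) / 100, 0.1)
})

test_that("analytic and simulated power agree within Monte-Carlo error", {
  for (s in list(c(events = 150, hr = 1.3), c(events = 250, hr = 1.2))) {
    run <- simulate_power(power_spec(n = 500, target_events = s[["events"]],
                                     effect = log(s[["hr"]]),
                                     replicates = 400, seed = 34))
    expect_lt(abs(run$power - run$analytic), 3 * run$mc_se + 0.01)
  }
})

test_that("linear-design power matches its normal approximation", {
  run <- simulate_power(power_spec(n = 400, effect = 0.15, var_x = 1,
                                   residual_sd = 1, replicates = 400,
                                   seed = 35), design = "linear")
  expect_lt(abs(run$power - run$analytic), 3 * run$mc_se + 0.01)
})

test_that("power specifications are validated", {
  expect_error(power_spec(alpha = 0), "alpha")
  expect_error(power_spec(power = 1), "power")
  expect_error(power_spec(replicates = 10), "replicates")
  expect_error(simulate_power(power_spec(n = 100, target_events = 200)),
               "target_events")
})
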