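test_that("driver generation is reproducible and respects degenerate configs", {
  p <- driver_params()
  d1 <- gen_drivers(p, "2020-01-01", "2020-02-01", seed = 5)
  d2 <- gen_drivers(p, "2020-01-01", "2020-02-01", seed = 5)
  expect_identical(d1, d2)

  flat <- driver_params(ta = list(seas_amp = 0, diur_amp = 0, sd = 0))
  d <- gen_drivers(flat, "2020-01-01", "2020-02-01", seed = 1)
  expect_true(all(d$TA == 3.5))

  expect_error(driver_params(ta = list(ar1 = 1)), "AR")
  expect_error(driver_params(ws = list(sd = -1)), "sd")
})

test_that("air-temperature AR(1) coefficient is recovered from the series", {
  p <- driver_params(ta = list(seas_amp = 0, diur_amp = 0, ar1 = 0.8, sd = 1))
  d <- gen_drivers(p, "2019-10-01", "2023-10-01", seed = 9)  # ~70k records
  a1 <- acf(d$TA, plot = FALSE, lag.max = 1)$acf[2]
  expect_lt(abs(a1 - 0.8), 0.05)
})

test_that("soil temperatures are damped, smoothed and lagged with depth", {
  d <- gen_drivers(driver_params(), "2020-01-01", "2021-01-01", seed = 2)
  expect_lt(sd(d$TS_70), sd(d$TS_5))
  expect_lt(sd(d$TS_5), sd(d$TA))
  # deeper layers peak later in the year
  expect_gt(which.max(d$TS_70), which.max(d$TS_5))
})

test_that("flux truth follows its closed form and the counterfactual identity", {
  ts <- halfhour_stamps("2021-01-01", 100)
  drv <- data.frame(timestamp = ts, SW_IN = 0, TA = 10, TS_20 = 8, WTD = 30)
  tr <- flux_truth_params(sd_co2 = 0, sd_ch4 = 0)
  fx <- gen_true_fluxes(drv, tr, null_treatment(), site_id = "t")
  # SW = 0, TA = 10: NEE is exactly the reference respiration
  expect_equal(fx$co2$factual$values, rep(tr$r_ref, 100), tolerance = 1e-12)
  expect_identical(fx$co2$factual$values, fx$co2$counterfactual$values)
  expect_identical(fx$ch4$factual$values, fx$ch4$counterfactual$values)
  # CH4 closed form
  expect_equal(fx$ch4$factual$values,
               rep(exp(tr$ch4_a + tr$ch4_b * 8 + tr$ch4_c * 30) -
                     tr$ch4_uptake, 100), tolerance = 1e-12)
})

test_that("treatment shifts the factual series only after the rewet date", {
  drv <- quick_drivers(120, "2021-08-01", seed = 4)
  tr <- flux_truth_params(sd_co2 = 0, sd_ch4 = 0)
  spec <- treatment_spec(rewet_date = "2021-10-01", resp_mult = 1.5,
                         gpp_mult = 1, ch4_mult = 1, wtd_shift = 0,
                         ramp_days = 0)
  fx <- gen_true_fluxes(drv, tr, spec, site_id = "t")
  pre <- drv$timestamp <= as.POSIXct("2021-10-01", tz = "UTC")
  expect_identical(fx$co2$factual$values[pre],
                   fx$co2$counterfactual$values[pre])
  # after: difference is exactly half the respiration term
  resp <- tr$r_ref * tr$q10^((drv$TA - 10) / 10)
  post <- !pre
  expect_equal(fx$co2$factual$values[post] -
                 fx$co2$counterfactual$values[post],
               0.5 * resp[post], tolerance = 1e-12)
})

test_that("degrade hits the target gap fraction in runs, reproducibly", {
  n <- 70000
  s <- halfhour_series("s", "x", halfhour_stamps("2019-10-01", n),
                       rnorm(n), "degC")
  expect_identical(degrade(s, 0), s)
  g1 <- degrade(s, 0.3, seed = 7)
  expect_lt(abs(mean(g1$gap_mask) - 0.3), 0.01)
  g2 <- degrade(s, 0.3, seed = 7)
  expect_identical(g1$gap_mask, g2$gap_mask)
  # gaps arrive in runs, not as independent drop-outs
  r <- rle(g1$gap_mask)
  expect_gt(mean(r$lengths[r$values]), 2)
  expect_error(degrade(s, 1), "gap_fraction")
})

test_that("raw windows realise their target covariance", {
  w <- gen_raw_window(raw_window_spec(cov_ch4 = 0.5, sd_ch4 = 2,
                                      ch4_mean = 10), seed = 21)
  expect_length(w$w, 36000)
  cv <- mean((w$ch4 - mean(w$ch4)) * (w$w - mean(w$w)))
  # tilt is zero by default so w is the aligned vertical wind
  expect_lt(abs(cv - 0.5), 0.05)

  w0 <- gen_raw_window(raw_window_spec(cov_ch4 = 0, sd_ch4 = 0.004), seed = 22)
  cv0 <- mean((w0$ch4 - mean(w0$ch4)) * (w0$w - mean(w0$w)))
  expect_lt(abs(cv0), 3 * 0.3 * 0.004 / sqrt(36000))
})

test_that("planted spikes are recorded and detectable", {
  w <- gen_raw_window(raw_window_spec(n_spikes = 10), seed = 23)
  expect_length(w$injected$spike_idx, 10)
  # every planted spike exceeds 3.5 local sd of a 5-min window
  ms_mean <- stats::filter(w$ch4, rep(1 / 6000, 6000), sides = 2)
  dev <- abs(w$ch4 - ms_mean)
  expect_true(all(dev[w$injected$spike_idx] > 3.5 * sd(w$ch4, na.rm = TRUE),
                  na.rm = TRUE))
})

test_that("the default campaign exports its truth and the injected effect", {
  camp <- simulate_campaign(seed = 3, start = "2020-10-01",
                            end = "2022-10-01", gap_fraction = 0.2,
                            treatment = treatment_spec(
                              rewet_date = "2021-10-01"))
  expect_named(camp$sites, c("control", "treatment"))
  # control site: no intervention, factual == counterfactual bitwise
  ctrl <- camp$sites$control$fluxes
  expect_identical(ctrl$co2$factual$values, ctrl$co2$counterfactual$values)
  # treatment site diverges and the exported effect is positive for CO2
  expect_gt(camp$truth$effect_gC$co2[["one_year"]], 0)
  expect_lt(abs(mean(camp$sites$treatment$observed$co2$gap_mask) - 0.2),
            0.01)
})
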