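test_that("water table depth is rejected as a model predictor", {
  drv <- quick_drivers(30, seed = 71)
  dm <- build_driver_matrix(drv)
  dm$WTD_1 <- drv$WTD
  fx <- gen_true_fluxes(drv, flux_truth_params(), null_treatment(),
                        site_id = "c")
  expect_error(
    train_period_models(fx$co2$factual, dm,
                        period_spec("2021-06-01", "2021-06-15", "2021-07-01"),
                        features = c(driver_features(), "WTD_1")),
    "water table depth", ignore.case = TRUE
  )
})

test_that("period models train on disjoint period records only", {
  drv <- quick_drivers(40, "2021-09-01", seed = 72)
  dm <- build_driver_matrix(drv)
  fx <- gen_true_fluxes(drv, flux_truth_params(),
                        treatment_spec(rewet_date = "2021-10-01"),
                        site_id = "t")
  obs <- degrade(fx$co2$factual, 0.2, seed = 1)
  periods <- period_spec("2021-09-01", "2021-10-01", "2021-10-11")
  pm <- train_period_models(obs, dm, periods, m = 5, n_burn = 20,
                           n_draws = 10, n_chains = 2, min_records = 100)
  n_pre <- sum(!obs$gap_mask &
                 obs$timestamps <= as.POSIXct("2021-10-01", tz = "UTC"))
  n_tr <- sum(!obs$gap_mask) - n_pre
  expect_identical(pm$pre_model$n, n_pre)
  expect_identical(pm$treatment_model$n, n_tr)

  # too few records in a period is an error
  expect_error(
    train_period_models(obs, dm, periods, min_records = 1e6),
    "valid records"
  )
})

test_that("effect arithmetic: cumulative difference and quadrature widths", {
  n <- 35040  # two 365-day years of half-hours
  cf <- make_cf_draws(actual_levels = rep(10.7, 3), cf_levels = rep(7.0, 3),
                      n = n)
  # constant draws scaled so the 2-year cumulative hits the given g C m-2
  prefix <- 1e-9
  scale <- 1 / (n * 1800 * 12.011 * prefix)
  cf$actual <- cf$actual * scale
  cf$counterfactual <- cf$counterfactual * scale
  ee <- effect_estimate(cf, eval_dates = cf$timestamps[n])
  expect_equal(ee$effects$effect, 10.7 - 7.0, tolerance = 1e-9)
  expect_equal(ee$effects$halfwidth, 0, tolerance = 1e-9)
  expect_equal(ee$effects$actual_cum, 10.7, tolerance = 1e-9)

  expect_equal(combine_halfwidths(15, 47), sqrt(15^2 + 47^2))
  expect_lt(abs(combine_halfwidths(15, 47) - 49.3), 0.05)

  expect_error(effect_estimate(cf, eval_dates = "2030-01-01"),
               "outside the treatment period")
})

test_that("identical actual and counterfactual draws give a null effect", {
  cf <- make_cf_draws(rep(2, 4), rep(2, 4), n = 200)
  ee <- effect_estimate(cf, eval_dates = cf$timestamps[150])
  expect_equal(ee$effects$effect, 0)
  expect_equal(ee$effects$halfwidth, 0)
})

test_that("effects are additive across evaluation dates per draw", {
  set.seed(73)
  n <- 400
  cf <- make_cf_draws(rep(1, 5), rep(1, 5), n = n)
  cf$actual <- matrix(rnorm(n * 5, 1), n, 5)
  cf$counterfactual <- matrix(rnorm(n * 5, 0.5), n, 5)
  d1 <- cf$timestamps[100]; d2 <- cf$timestamps[300]
  ee <- effect_estimate(cf, eval_dates = c(d1, d2))
  # per-draw: difference at d2 = difference at d1 + year-2 accumulation
  inc <- ee$diff_draws[2, ] - ee$diff_draws[1, ]
  cum_a <- ee$cum_actual; cum_c <- ee$cum_counterfactual
  expect_equal(inc, (cum_a[300, ] - cum_a[100, ]) - (cum_c[300, ] - cum_c[100, ]),
               tolerance = 1e-12)
  expect_equal(ee$effects$effect[2] - ee$effects$effect[1], mean(inc),
               tolerance = 1e-12)
})

test_that("counterfactual pipeline recovers an injected respiration step", {
  drv <- gen_drivers(driver_params(), "2020-10-01", "2022-10-01", seed = 74)
  dm <- build_driver_matrix(drv)
  spec <- treatment_spec(rewet_date = "2021-10-01", resp_mult = 1.5,
                         gpp_mult = 0.9, wtd_shift = 0, ramp_days = 30)
  fx <- gen_true_fluxes(drv, flux_truth_params(), spec, site_id = "t")
  obs <- degrade(fx$co2$factual, 0.3, seed = 2)
  periods <- period_spec("2020-10-01", "2021-10-01", "2022-10-01")
  pm <- train_period_models(obs, dm, periods, m = 25, n_burn = 100,
                           n_draws = 200, n_chains = 2, seed = 8)
  tr_rows <- in_treatment <- dm$timestamp > as.POSIXct("2021-10-01",
                                                       tz = "UTC")
  cfp <- predict_actual_and_counterfactual(pm, dm[tr_rows, ])
  ee <- effect_estimate(cfp, eval_dates = "2022-10-01")

  truth_cum <- cumsum((fx$co2$mu_factual - fx$co2$mu_counterfactual) *
                        1800 * 12.011e-6)
  truth <- truth_cum[length(truth_cum)]
  expect_gt(truth, 50)  # the injected effect is material
  expect_lt(abs(ee$effects$effect - truth) / truth, 0.2)
  expect_true(ee$effects$p5 <= truth && truth <= ee$effects$p95)

  # counterfactual tracks the pre-treatment regime: it must sit well below
  # the actual cumulative under a positive respiration step
  expect_gt(ee$effects$actual_cum, ee$effects$counterfactual_cum)

  expect_error(predict_actual_and_counterfactual(pm, dm[0, ]), "empty")
})

test_that("a no-effect site yields indistinguishable period models", {
  drv <- gen_drivers(driver_params(), "2020-10-01", "2022-10-01", seed = 75)
  dm <- build_driver_matrix(drv)
  fx <- gen_true_fluxes(drv, flux_truth_params(), null_treatment(),
                        site_id = "c")
  obs <- degrade(fx$co2$factual, 0.3, seed = 3)
  periods <- period_spec("2020-10-01", "2021-10-01", "2022-10-01")
  pm <- train_period_models(obs, dm, periods, m = 25, n_burn = 100,
                           n_draws = 100, n_chains = 2, seed = 9)
  tr_rows <- dm$timestamp > as.POSIXct("2021-10-01", tz = "UTC")
  cfp <- predict_actual_and_counterfactual(pm, dm[tr_rows, ])
  pm_a <- rowMeans(cfp$actual)
  pm_c <- rowMeans(cfp$counterfactual)
  expect_lt(abs(mean(pm_a - pm_c)), 0.15)  # umol scale, noise sd = 2

  cv <- control_validation(pm, dm[tr_rows, ], eval_dates = "2022-10-01")
  expect_true(is.finite(cv$actual_cum))
  expect_lt(abs(cv$actual_cum - cv$predicted_cum),
            3 * (cv$p95 - cv$p5))
})
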