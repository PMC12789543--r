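test_that("double rotation zeroes the crosswind and vertical means", {
  w <- gen_raw_window(raw_window_spec(tilt_yaw = 0.2, tilt_pitch = 0.1),
                      seed = 31)
  r <- double_rotation(w)
  mag <- sqrt(mean(w$u)^2 + mean(w$v)^2 + mean(w$w)^2)
  expect_lt(abs(mean(r$window$v)), 1e-12 * mag)
  expect_lt(abs(mean(r$window$w)), 1e-12 * mag)
  # injected tilt angles are recovered (up to sampling noise in the means)
  expect_lt(abs(r$yaw - 0.2), 1e-2)
  expect_lt(abs(r$pitch - 0.1), 1e-2)
  # isometry: per-sample wind speed preserved
  s0 <- sqrt(w$u^2 + w$v^2 + w$w^2)
  s1 <- sqrt(r$window$u^2 + r$window$v^2 + r$window$w^2)
  expect_lt(max(abs(s1 - s0) / s0), 1e-10)
})

test_that("aligned flow gets an identity rotation", {
  w <- gen_raw_window(raw_window_spec(), seed = 32)
  r <- double_rotation(w)
  expect_lt(abs(r$yaw), 0.01)
  expect_lt(abs(r$pitch), 0.01)

  w$u <- w$u * 0; w$v <- w$v * 0; w$w <- w$w * 0
  expect_error(double_rotation(w), "zero mean wind")
})

test_that("block covariance flux recovers the target and handles lags", {
  w <- gen_raw_window(raw_window_spec(cov_ch4 = 0.5, sd_ch4 = 2,
                                      ch4_mean = 10), seed = 33)
  r <- double_rotation(w)
  expect_lt(abs(block_covariance_flux(r$window, "ch4") - 0.5), 0.05)

  # constant scalar has exactly zero flux
  r$window$ch4 <- rep(10, length(r$window$ch4))
  expect_identical(block_covariance_flux(r$window, "ch4"), 0)

  # shifting the scalar by k samples and compensating with lag = k
  w2 <- gen_raw_window(raw_window_spec(cov_ch4 = 0.5, sd_ch4 = 2,
                                       ch4_mean = 10), seed = 34)
  r2 <- double_rotation(w2)
  f0 <- block_covariance_flux(r2$window, "ch4")
  k <- 40
  shifted <- r2$window
  n <- length(shifted$ch4)
  shifted$ch4 <- c(rep(shifted$ch4[1], k), shifted$ch4[1:(n - k)])
  expect_lt(abs(block_covariance_flux(shifted, "ch4", lag_samples = k) - f0),
            0.01)
  expect_error(block_covariance_flux(r2$window, "ch4", lag_samples = 4000),
               "lag")
})

test_that("WPL correction matches hand arithmetic and its limits", {
  air <- list(T_k = 283, rho_d = 1.2, rho_v = 0.008, rho_m = 5200)
  expect_identical(wpl_ch4(10, 0, 0, air), 10)

  mu <- 28.9647 / 18.01528
  hand <- 10 + mu * (5200 / 1.2) * 5e-5 +
    (1 + mu * 0.008 / 1.2) * (5200 / 283) * (50 / ((1.2 + 0.008) * 1005))
  expect_equal(wpl_ch4(10, 50, 5e-5, air), hand, tolerance = 1e-12)

  # correction terms are linear in the gas density
  air2 <- air; air2$rho_m <- 2 * air$rho_m
  expect_equal(wpl_ch4(10, 50, 5e-5, air2) - 10,
               2 * (wpl_ch4(10, 50, 5e-5, air) - 10), tolerance = 1e-12)

  expect_error(wpl_ch4(10, 0, 0, list(T_k = 283, rho_d = -1, rho_v = 0,
                                      rho_m = 1)), "nonphysical")
})

test_that("Vickers-Mahrt battery passes clean data and catches defects", {
  clean <- vickers_mahrt(gen_raw_window(raw_window_spec(), seed = 35))
  expect_false(attr(clean, "hard_fail"))

  spiked <- vickers_mahrt(gen_raw_window(raw_window_spec(n_spikes = 400),
                                         seed = 36))
  row <- spiked[spiked$channel == "ch4" & spiked$test == "spikes", ]
  expect_false(row$pass)
  expect_gt(row$statistic, 0.01)

  dropped <- vickers_mahrt(gen_raw_window(raw_window_spec(dropout_len = 5000),
                                          seed = 37))
  expect_false(dropped[dropped$channel == "ch4" &
                         dropped$test == "dropouts", "pass"])

  # constant channel: zero amplitude resolution
  w <- gen_raw_window(raw_window_spec(), seed = 38)
  w$ch4 <- rep(0.08, length(w$ch4))
  const <- vickers_mahrt(w)
  expect_false(const[const$channel == "ch4" & const$test == "amplitude",
                     "pass"])

  w$ch4 <- rep(NA_real_, length(w$ch4))
  expect_true(attr(vickers_mahrt(w), "hard_fail"))
})

test_that("Foken-Wichura stationarity flagging", {
  w <- gen_raw_window(raw_window_spec(cov_ch4 = 0.5, sd_ch4 = 2,
                                      ch4_mean = 10), seed = 39)
  r <- double_rotation(w)
  fw <- foken_wichura(r$window, "ch4")
  expect_lt(fw$rn_cov, 30)
  expect_identical(fw$flag, 0L)

  # correlated mean step in both w and scalar: nonstationary record
  # (applied to a default low-covariance window so the spurious covariance
  # dominates the block statistic)
  wd <- gen_raw_window(raw_window_spec(), seed = 42)
  n <- length(wd$ch4)
  step <- rep(c(-0.5, 0.5), each = n / 2)
  wd$ch4 <- wd$ch4 + 0.02 * step
  wd$w <- wd$w + 0.3 * step
  fw2 <- foken_wichura(double_rotation(wd)$window, "ch4")
  expect_gte(fw2$flag, 1L)

  # six identical sub-blocks: RN exactly 0
  w3 <- gen_raw_window(raw_window_spec(), seed = 40)
  block <- 36000 / 6
  w3$w <- rep(w3$w[1:block], 6)
  w3$ch4 <- rep(w3$ch4[1:block], 6)
  fw3 <- foken_wichura(w3, "ch4")
  expect_equal(fw3$rn_cov, 0, tolerance = 1e-9)

  # zero block covariance
  w3$ch4 <- rep(0.08, 36000)
  fw4 <- foken_wichura(w3, "ch4")
  expect_identical(fw4$flag, 2L)
  expect_identical(fw4$rn_cov, Inf)
})

test_that("record filter keeps only flag-0, windy, clean records", {
  est <- list(fake_estimate(1.4, 0), fake_estimate(2.0, 1),
              fake_estimate(2.0, 0), fake_estimate(2.0, 0, vm = FALSE))
  out <- filter_fluxes(est)
  expect_length(out$retained, 1)
  expect_equal(out$discarded$reason, c("wind", "stationarity", "vm"))

  # idempotent and order-independent
  again <- filter_fluxes(out$retained)
  expect_length(again$retained, 1)
  expect_equal(nrow(again$discarded), 0)
  rev_out <- filter_fluxes(rev(est))
  expect_length(rev_out$retained, 1)
})

test_that("full window pipeline produces a usable flux estimate", {
  w <- gen_raw_window(raw_window_spec(tilt_pitch = 0.05), seed = 41)
  fe <- process_raw_window(w, "ch4")
  expect_s3_class(fe, "flux_estimate")
  expect_lt(abs(fe$flux - 5e-4) / 5e-4, 0.1)
  expect_true(fe$vm_pass)
  expect_identical(fe$fw_flag, 0L)
  expect_gt(fe$wind_speed, 1.5)
})

test_that("independent wind and scalar give zero flux within Monte Carlo error", {
  fluxes <- vapply(1:12, function(s) {
    w <- gen_raw_window(raw_window_spec(cov_ch4 = 0, sd_ch4 = 1,
                                        ch4_mean = 10), seed = 100 + s)
    block_covariance_flux(double_rotation(w)$window, "ch4")
  }, numeric(1))
  se <- 0.3 * 1 / sqrt(36000)
  expect_true(all(abs(fluxes) < 3 * se))
})
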