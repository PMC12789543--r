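# Shared fixture builders; everything is generated in code at test time.

halfhour_stamps <- function(start, n) {
  as.POSIXct(start, tz = "UTC") + 1800 * seq_len(n)
}

# constant-flux series whose cumulative curve hits `target_gC` after n steps
constant_flux_series <- function(target_gC, n, units, start = "2021-10-01",
                                 site = "s", var = "flux") {
  prefix <- if (units == "umol m-2 s-1") 1e-6 else 1e-9
  value <- target_gC / (n * 1800 * 12.011 * prefix)
  halfhour_series(site, var, halfhour_stamps(start, n), rep(value, n), units)
}

# hand-assembled cf_draws pair with constant per-draw flux levels
make_cf_draws <- function(actual_levels, cf_levels, n, units = "nmol m-2 s-1",
                          start = "2021-10-01") {
  structure(list(
    timestamps = halfhour_stamps(start, n),
    actual = matrix(rep(actual_levels, each = n), n,
                    length(actual_levels)),
    counterfactual = matrix(rep(cf_levels, each = n), n, length(cf_levels)),
    gas = "F_CH4", units = units, site_id = "treatment"
  ), class = "cf_draws")
}

# small driver table with every column the flux models need
quick_drivers <- function(n_days = 30, start = "2021-06-01", seed = 1) {
  gen_drivers(driver_params(), start,
              as.POSIXct(start, tz = "UTC") + n_days * 86400, seed = seed)
}

# flux estimate stub for filter tests
fake_estimate <- function(wind, flag, vm = TRUE) {
  structure(list(gas = "ch4", flux = 1, wind_speed = wind, fw_flag = flag,
                 rn_cov = 0, vm_pass = vm), class = "flux_estimate")
}
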