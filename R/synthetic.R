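# Synthetic two-site campaign generator. Emulates the statistical structure
# of a boreal peatland eddy-covariance campaign: harmonically forced,
# AR(1)-noised drivers; a rectangular-hyperbola + Q10 CO2 truth; a
# log-linear soil-temperature / water-table CH4 truth; a step treatment with
# a short ramp at the rewetting date; gappy observation masks; and 20 Hz
# raw windows with known covariance targets and planted QC defects.

#' Driver-process parameters for the campaign generator
#'
#' Each meteorological variable is generated as
#' `mean + seasonal harmonic + diurnal harmonic + AR(1) noise`, optionally
#' clipped below. Soil temperatures are exponentially damped, low-pass
#' filtered copies of the air-temperature anomaly, so they are smoother,
#' lagged, and of decreasing amplitude with depth. Precipitation follows a
#' two-state (wet/dry) Markov chain with exponential event depths; the
#' defaults give an annual total near 950 mm, the regional norm. Water
#' table depth (cm below surface, positive downward) gets its own seasonal
#' harmonic and slow AR(1) noise.
#'
#' @param ... named lists overriding the per-variable defaults; each
#'   harmonic variable takes fields `mean`, `seas_amp`, `seas_peak` (day of
#'   year), `diur_amp`, `diur_peak` (hour), `ar1` (in `[0,1)`), `sd`
#'   (innovation sd, `>= 0`) and optional `min` clip.
#' @return An object of class `"driver_params"`.
#' @export
driver_params <- function(...) {
  p <- list(
    ta  = list(mean = 3.5, seas_amp = 9, seas_peak = 200, diur_amp = 3.5,
               diur_peak = 14, ar1 = 0.95, sd = 0.8),
    sw  = list(mean = 120, seas_amp = 110, seas_peak = 172, diur_amp = 250,
               diur_peak = 12.5, ar1 = 0.9, sd = 30, min = 0),
    lw  = list(mean = 310, seas_amp = 40, seas_peak = 200, diur_amp = 8,
               diur_peak = 15, ar1 = 0.98, sd = 8),
    pa  = list(mean = 94, seas_amp = 0.4, seas_peak = 30, diur_amp = 0.05,
               diur_peak = 10, ar1 = 0.995, sd = 0.05),
    vpd = list(mean = 0.25, seas_amp = 0.2, seas_peak = 190, diur_amp = 0.25,
               diur_peak = 15, ar1 = 0.9, sd = 0.08, min = 0),
    ws  = list(mean = 2.8, seas_amp = 0.5, seas_peak = 20, diur_amp = 0.8,
               diur_peak = 14, ar1 = 0.9, sd = 0.8, min = 0.1),
    soil = list(depths_cm = c(5, 10, 20, 40, 70), damping_depth_cm = 100,
                tau0_days = 2, tau_per_m_days = 60),
    precip = list(p_wet_start = 0.035, p_wet_stay = 0.75,
                  mean_depth_mm = 0.45),
    wtd = list(mean = 30, seas_amp = 6, seas_peak = 210, diur_amp = 0,
               diur_peak = 0, ar1 = 0.995, sd = 0.15)
  )
  ov <- list(...)
  for (nm in names(ov)) {
    if (!nm %in% names(p)) stop("unknown driver parameter block '", nm, "'")
    p[[nm]] <- utils::modifyList(p[[nm]], ov[[nm]])
  }
  for (nm in c("ta", "sw", "lw", "pa", "vpd", "ws", "wtd")) {
    v <- p[[nm]]
    if (v$ar1 < 0 || v$ar1 >= 1) stop(nm, ": AR(1) coefficient must be in [0,1)")
    if (v$sd < 0) stop(nm, ": innovation sd must be >= 0")
  }
  if (p$soil$damping_depth_cm <= 0) stop("soil damping depth must be > 0")
  structure(p, class = "driver_params")
}

harmonic_ar1 <- function(v, doy, hod, n) {
  x <- v$mean +
    v$seas_amp * cos(2 * pi * (doy - v$seas_peak) / 365.25) +
    v$diur_amp * cos(2 * pi * (hod - v$diur_peak) / 24)
  if (v$sd > 0) {
    e <- as.numeric(filter(rnorm(n, 0, v$sd), v$ar1, method = "recursive"))
    x <- x + e
  }
  if (!is.null(v$min)) x <- pmax(x, v$min)
  x
}

markov_precip <- function(v, n) {
  wet <- logical(n)
  u <- runif(n)
  state <- FALSE
  for (i in seq_len(n)) {
    state <- if (state) u[i] < v$p_wet_stay else u[i] < v$p_wet_start
    wet[i] <- state
  }
  out <- numeric(n)
  out[wet] <- rexp(sum(wet), rate = 1 / v$mean_depth_mm)
  out
}

# exponential moving average, alpha derived from a time constant in days
ema <- function(x, tau_days, dt_hours = 0.5) {
  a <- 1 - exp(-dt_hours / (tau_days * 24))
  as.numeric(filter(a * x, 1 - a, method = "recursive"))
}

#' Generate the meteorological driver series for one site
#'
#' Produces the full half-hourly driver table over `[start, end)`:
#' shortwave and longwave incoming radiation, air temperature and
#' pressure, vapour pressure deficit, wind speed, soil temperature at five
#' depths, precipitation, and water table depth. Timestamps label the end
#' of each 30-minute interval. Reproducible for a fixed `(params, seed)`.
#'
#' @param params a [driver_params()].
#' @param start,end period boundaries (UTC instants or parseable strings);
#'   `end` exclusive.
#' @param seed optional integer seed.
#' @return data frame with `timestamp`, `SW_IN`, `LW_IN`, `TA`, `PA`,
#'   `VPD`, `WS`, `TS_5` .. `TS_70`, `P_RAIN`, `WTD`.
#' @export
gen_drivers <- function(params = driver_params(), start = "2019-10-01",
                        end = "2023-10-01", seed = NULL) {
  stopifnot(inherits(params, "driver_params"))
  if (!is.null(seed)) set.seed(seed)
  start <- as.POSIXct(start, tz = "UTC")
  end <- as.POSIXct(end, tz = "UTC")
  n <- as.numeric(difftime(end, start, units = "secs")) / 1800
  stopifnot(n == round(n), n > 0)
  ts <- start + 1800 * seq_len(n)   # end-of-interval convention
  lt <- as.POSIXlt(ts - 900, tz = "UTC")  # interval midpoints drive forcing
  doy <- lt$yday + 1
  hod <- lt$hour + lt$min / 60

  ta <- harmonic_ar1(params$ta, doy, hod, n)
  out <- data.frame(
    timestamp = ts,
    SW_IN = harmonic_ar1(params$sw, doy, hod, n),
    LW_IN = harmonic_ar1(params$lw, doy, hod, n),
    TA = ta,
    PA = harmonic_ar1(params$pa, doy, hod, n),
    VPD = harmonic_ar1(params$vpd, doy, hod, n),
    WS = harmonic_ar1(params$ws, doy, hod, n)
  )
  anom <- ta - mean(ta)
  for (z in params$soil$depths_cm) {
    tau <- params$soil$tau0_days + params$soil$tau_per_m_days * z / 100
    damp <- exp(-z / params$soil$damping_depth_cm)
    out[[paste0("TS_", z)]] <- mean(ta) + damp * ema(anom, tau)
  }
  out$P_RAIN <- markov_precip(params$precip, n)
  out$WTD <- harmonic_ar1(params$wtd, doy, hod, n)
  out
}

#' Flux-truth parameters of the generator
#'
#' The deterministic flux structure the statistical models are asked to
#' learn. CO2 net ecosystem exchange is respiration minus a
#' rectangular-hyperbola light response,
#' `NEE = -alpha*SW*gpp_max/(alpha*SW + gpp_max) + r_ref*q10^((TA-10)/10)`,
#' in umol m-2 s-1 (positive = emission). CH4 flux is log-linear in soil
#' temperature and water table depth,
#' `F = exp(a + b*TS + c*WTD) - uptake`, in nmol m-2 s-1; the small
#' `uptake` offset allows the weak non-growing-season uptake seen at
#' drained sites. Gaussian observation noise is added per gas.
#'
#' @param alpha initial slope of the light response (umol CO2 per W m-2).
#' @param gpp_max light-saturated gross uptake (umol m-2 s-1), `> 0`.
#' @param r_ref respiration at 10 degC (umol m-2 s-1), `> 0`.
#' @param q10 respiration temperature sensitivity, `> 0`.
#' @param ch4_a,ch4_b,ch4_c CH4 log-rate intercept, soil-temperature
#'   sensitivity (per degC) and water-table sensitivity (per cm, negative:
#'   deeper water table, less CH4).
#' @param ch4_uptake constant uptake offset (nmol m-2 s-1).
#' @param ch4_soil_depth which soil-temperature depth (cm) drives CH4.
#' @param sd_co2,sd_ch4 observation noise sd per gas (umol / nmol).
#' @return An object of class `"flux_truth_params"`.
#' @export
flux_truth_params <- function(alpha = 0.025, gpp_max = 5.5, r_ref = 2.5,
                              q10 = 2.2, ch4_a = 2.7, ch4_b = 0.12,
                              ch4_c = -0.03, ch4_uptake = 2,
                              ch4_soil_depth = 20,
                              sd_co2 = 2, sd_ch4 = 5) {
  stopifnot(gpp_max > 0, r_ref > 0, q10 > 0, sd_co2 >= 0, sd_ch4 >= 0)
  structure(list(alpha = alpha, gpp_max = gpp_max, r_ref = r_ref, q10 = q10,
                 ch4_a = ch4_a, ch4_b = ch4_b, ch4_c = ch4_c,
                 ch4_uptake = ch4_uptake, ch4_soil_depth = ch4_soil_depth,
                 sd_co2 = sd_co2, sd_ch4 = sd_ch4),
            class = "flux_truth_params")
}

#' Treatment (rewetting) specification
#'
#' The injected intervention: multiplicative changes to respiration, gross
#' uptake and the CH4 rate, plus a water-table shift (cm; negative = the
#' water table rises), all ramping linearly from no effect at `rewet_date`
#' to full effect `ramp_days` later. All multipliers are identically 1
#' before the rewetting date, so factual and counterfactual series agree
#' bitwise there. `null_treatment()` is the no-intervention control.
#'
#' @param rewet_date treatment instant (default [rewetting_date()]).
#' @param resp_mult,gpp_mult,ch4_mult multipliers, `> 0`.
#' @param wtd_shift water-table shift in cm (negative = rise).
#' @param ramp_days length of the linear ramp-in (days).
#' @return An object of class `"treatment_spec"`.
#' @export
treatment_spec <- function(rewet_date = rewetting_date(), resp_mult = 1.06,
                           gpp_mult = 0.99, ch4_mult = 1.15,
                           wtd_shift = -9, ramp_days = 60) {
  stopifnot(resp_mult > 0, gpp_mult > 0, ch4_mult > 0, ramp_days >= 0)
  structure(list(rewet_date = as.POSIXct(rewet_date, tz = "UTC"),
                 resp_mult = resp_mult, gpp_mult = gpp_mult,
                 ch4_mult = ch4_mult, wtd_shift = wtd_shift,
                 ramp_days = ramp_days),
            class = "treatment_spec")
}

#' @rdname treatment_spec
#' @export
null_treatment <- function(rewet_date = rewetting_date()) {
  treatment_spec(rewet_date, resp_mult = 1, gpp_mult = 1, ch4_mult = 1,
                 wtd_shift = 0, ramp_days = 0)
}

# ramp from 0 (before rewetting) to 1 (ramp_days after)
treatment_ramp <- function(timestamps, spec) {
  dt_days <- as.numeric(difftime(timestamps, spec$rewet_date, units = "days"))
  if (spec$ramp_days == 0) as.numeric(dt_days > 0)
  else pmin(pmax(dt_days / spec$ramp_days, 0), 1)
}

#' Generate paired factual / counterfactual flux series
#'
#' Applies the flux-truth model to a driver table, once with the treatment
#' applied (factual) and once with all multipliers held at 1
#' (counterfactual). Both share the same observation-noise realisation, so
#' they agree bitwise before the rewetting date. The noiseless mean
#' functions are returned alongside, so effect-recovery tests can compute
#' the injected cumulative effect without re-deriving the generator.
#'
#' @param drivers a [gen_drivers()] table.
#' @param truth a [flux_truth_params()].
#' @param treatment a [treatment_spec()].
#' @param site_id site label for the produced series.
#' @param seed optional integer seed (controls the noise realisation).
#' @return list with per-gas elements `co2`, `ch4`, each containing
#'   `factual` and `counterfactual` [halfhour_series()] and `mu_factual`,
#'   `mu_counterfactual` noiseless mean vectors; plus `wtd_factual`, the
#'   treatment-shifted water-table series.
#' @export
gen_true_fluxes <- function(drivers, truth = flux_truth_params(),
                            treatment = treatment_spec(),
                            site_id = "site", seed = NULL) {
  stopifnot(inherits(truth, "flux_truth_params"),
            inherits(treatment, "treatment_spec"))
  if (!is.null(seed)) set.seed(seed)
  ts <- drivers$timestamp
  ramp <- treatment_ramp(ts, treatment)
  resp_m <- 1 + ramp * (treatment$resp_mult - 1)
  gpp_m <- 1 + ramp * (treatment$gpp_mult - 1)
  ch4_m <- 1 + ramp * (treatment$ch4_mult - 1)
  wtd_cf <- drivers$WTD
  wtd_f <- drivers$WTD + ramp * treatment$wtd_shift

  den <- truth$alpha * drivers$SW_IN + truth$gpp_max
  gpp <- ifelse(den == 0, 0, truth$alpha * drivers$SW_IN * truth$gpp_max / den)
  resp <- truth$r_ref * truth$q10^((drivers$TA - 10) / 10)
  mu_f_co2 <- -gpp * gpp_m + resp * resp_m
  mu_cf_co2 <- -gpp + resp

  tsoil <- drivers[[paste0("TS_", truth$ch4_soil_depth)]]
  mu_f_ch4 <- exp(truth$ch4_a + truth$ch4_b * tsoil + truth$ch4_c * wtd_f) *
    ch4_m - truth$ch4_uptake
  mu_cf_ch4 <- exp(truth$ch4_a + truth$ch4_b * tsoil + truth$ch4_c * wtd_cf) -
    truth$ch4_uptake

  n <- length(ts)
  e_co2 <- rnorm(n, 0, truth$sd_co2)
  e_ch4 <- rnorm(n, 0, truth$sd_ch4)

  list(
    co2 = list(
      factual = halfhour_series(site_id, "NEE_CO2", ts, mu_f_co2 + e_co2,
                                "umol m-2 s-1"),
      counterfactual = halfhour_series(site_id, "NEE_CO2", ts,
                                       mu_cf_co2 + e_co2, "umol m-2 s-1"),
      mu_factual = mu_f_co2, mu_counterfactual = mu_cf_co2
    ),
    ch4 = list(
      factual = halfhour_series(site_id, "F_CH4", ts, mu_f_ch4 + e_ch4,
                                "nmol m-2 s-1"),
      counterfactual = halfhour_series(site_id, "F_CH4", ts,
                                       mu_cf_ch4 + e_ch4, "nmol m-2 s-1"),
      mu_factual = mu_f_ch4, mu_counterfactual = mu_cf_ch4
    ),
    wtd_factual = halfhour_series(site_id, "WTD", ts, wtd_f, "cm")
  )
}

#' Knock gaps into a series, emulating QC rejection
#'
#' Masks a target fraction of records as missing, in runs: a mixture of
#' short outages (instrument glitches, mean 3 records) and multi-day
#' blocks (power or logger failures, mean 2 days). The realised gap
#' fraction is within 1/n of the target; a fixed seed reproduces the exact
#' pattern.
#'
#' @param series a [halfhour_series()].
#' @param gap_fraction target gap fraction, in `[0, 1)`.
#' @param seed optional integer seed.
#' @param p_long probability a gap run is a multi-day block.
#' @return the series with `NA` gaps inserted.
#' @export
degrade <- function(series, gap_fraction, seed = NULL, p_long = 0.15) {
  stopifnot(inherits(series, "halfhour_series"))
  if (gap_fraction < 0 || gap_fraction >= 1)
    stop("gap_fraction must be in [0, 1)")
  if (gap_fraction == 0) return(series)
  if (!is.null(seed)) set.seed(seed)
  n <- length(series$values)
  target <- round(gap_fraction * n)
  gap <- logical(n)
  count <- 0L
  while (count < target) {
    len <- if (runif(1) < p_long) 1 + rgeom(1, 1 / 96) else 1 + rgeom(1, 1 / 3)
    len <- min(len, target - count)
    start <- sample.int(n - len + 1, 1)
    gap[start:(start + len - 1)] <- TRUE
    count <- sum(gap)
  }
  series$values[gap] <- NA
  series$gap_mask <- is.na(series$values)
  series
}

#' Specification of a 20 Hz raw eddy-covariance window
#'
#' One 30-minute, 20 Hz (36 000 sample) record of wind components and
#' scalar channels with controllable turbulent covariances, mean wind,
#' anemometer tilt, and planted QC defects (spikes, dropouts) at indices
#' recorded in the output for oracle tests.
#'
#' @param mean_wind mean wind vector `c(u, v, w)` in the true (aligned)
#'   frame, m s-1.
#' @param tilt_yaw,tilt_pitch anemometer tilt angles (radians) applied to
#'   the aligned field before "measurement".
#' @param cov_ch4,cov_t,cov_q,cov_co2 target covariances of w' with the
#'   CH4, sonic-temperature, H2O and CO2 channels.
#' @param sd_u,sd_v,sd_w,sd_ts,sd_co2,sd_h2o,sd_ch4 channel fluctuation
#'   standard deviations.
#' @param ts_mean,co2_mean,h2o_mean,ch4_mean channel means (K,
#'   umol mol-1, mmol mol-1, mmol m-3).
#' @param n_spikes number of spikes planted in the CH4 channel.
#' @param dropout_len length (samples) of a constant-hold dropout planted
#'   in the CH4 channel (0 = none).
#' @param hz,duration_s sampling rate and window length.
#' @return An object of class `"raw_window_spec"`.
#' @export
raw_window_spec <- function(mean_wind = c(2.5, 0, 0), tilt_yaw = 0,
                            tilt_pitch = 0, cov_ch4 = 5e-4, cov_t = 0.02,
                            cov_q = 0.01, cov_co2 = -0.2, sd_u = 0.6,
                            sd_v = 0.5, sd_w = 0.3, sd_ts = 0.3,
                            sd_co2 = 2, sd_h2o = 0.3, sd_ch4 = 0.004,
                            ts_mean = 285, co2_mean = 410, h2o_mean = 10,
                            ch4_mean = 0.08, n_spikes = 0, dropout_len = 0,
                            hz = 20, duration_s = 1800) {
  stopifnot(is.finite(cov_ch4), is.finite(cov_t), is.finite(cov_q),
            is.finite(cov_co2), hz > 0, duration_s > 0)
  structure(as.list(environment()), class = "raw_window_spec")
}

# scalar channel with (near-)exact sample covariance against w'
scalar_channel <- function(wf, target_cov, sd_total, mean_val, n) {
  vw <- mean(wf^2) - mean(wf)^2
  slope <- target_cov / vw
  resid_sd <- sqrt(max(sd_total^2 - slope^2 * vw, (0.05 * sd_total)^2))
  mean_val + slope * (wf - mean(wf)) + rnorm(n, 0, resid_sd)
}

#' Generate a raw 20 Hz window
#'
#' Realises a [raw_window_spec()]: Gaussian turbulent fluctuations with
#' the requested w'-scalar covariances (sample covariance lands within a
#' fraction of a percent of target at 36 000 samples), mean wind and tilt
#' applied, and spikes/dropouts planted at recorded indices.
#'
#' @param spec a [raw_window_spec()].
#' @param seed optional integer seed.
#' @return An object of class `"raw_window"`: list of channels `u`, `v`,
#'   `w` (m s-1), `ts` (K), `co2`, `h2o`, `ch4`, with an `injected`
#'   element recording the construction (tilt angles, targets, spike and
#'   dropout indices).
#' @export
gen_raw_window <- function(spec = raw_window_spec(), seed = NULL) {
  stopifnot(inherits(spec, "raw_window_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$hz * spec$duration_s
  wf <- rnorm(n, 0, spec$sd_w)
  ua <- spec$mean_wind[1] + rnorm(n, 0, spec$sd_u)
  va <- spec$mean_wind[2] + rnorm(n, 0, spec$sd_v)
  wa <- spec$mean_wind[3] + wf

  ts <- scalar_channel(wf, spec$cov_t, spec$sd_ts, spec$ts_mean, n)
  co2 <- scalar_channel(wf, spec$cov_co2, spec$sd_co2, spec$co2_mean, n)
  h2o <- scalar_channel(wf, spec$cov_q, spec$sd_h2o, spec$h2o_mean, n)
  ch4 <- scalar_channel(wf, spec$cov_ch4, spec$sd_ch4, spec$ch4_mean, n)

  spike_idx <- integer(0)
  if (spec$n_spikes > 0) {
    # well-separated single-point spikes (>= 100 samples apart), 8 sd
    grid <- seq(51L, n - 50L, by = 80L)
    spike_idx <- sort(sample(grid, spec$n_spikes))
    ch4[spike_idx] <- ch4[spike_idx] +
      8 * spec$sd_ch4 * rep_len(c(1, -1), length(spike_idx))
  }
  dropout_idx <- integer(0)
  if (spec$dropout_len > 0) {
    start <- sample.int(n - spec$dropout_len, 1)
    dropout_idx <- start:(start + spec$dropout_len - 1)
    ch4[dropout_idx] <- ch4[start]
  }

  # tilt the aligned wind field: inverse pitch then inverse yaw
  cp <- cos(spec$tilt_pitch); sp <- sin(spec$tilt_pitch)
  u1 <- ua * cp - wa * sp
  w1 <- ua * sp + wa * cp
  cy <- cos(spec$tilt_yaw); sy <- sin(spec$tilt_yaw)
  u <- u1 * cy - va * sy
  v <- u1 * sy + va * cy

  structure(list(u = u, v = v, w = w1, ts = ts, co2 = co2, h2o = h2o,
                 ch4 = ch4, hz = spec$hz,
                 injected = list(tilt_yaw = spec$tilt_yaw,
                                 tilt_pitch = spec$tilt_pitch,
                                 cov_ch4 = spec$cov_ch4, cov_t = spec$cov_t,
                                 cov_q = spec$cov_q, cov_co2 = spec$cov_co2,
                                 spike_idx = spike_idx,
                                 dropout_idx = dropout_idx)),
            class = "raw_window")
}

#' Simulate a full two-site, multi-year campaign
#'
#' The default campaign is a two-site design (a control
#' that stays drained and a treatment site rewetted at 1 October 2021),
#' four hydrological years of half-hourly CO2 and CH4 fluxes driven by the
#' same driver process, a known injected treatment effect at the treatment
#' site only, QC-like gaps, and five water-table wells per site. The
#' generator truth (parameters, noiseless mean functions, injected
#' cumulative effect) is exported alongside the data so recovery tests
#' never re-derive it.
#'
#' @param seed integer seed governing everything.
#' @param start,end campaign period (defaults: the four study years).
#' @param params a [driver_params()].
#' @param truth a [flux_truth_params()].
#' @param treatment a [treatment_spec()] applied at the treatment site.
#' @param gap_fraction gap fraction knocked into each observed flux series.
#' @param n_wells water-table wells per site.
#' @return list with `sites` (per site: `drivers`, per-gas factual /
#'   counterfactual series, observed gappy series, `wells`) and `truth`
#'   (all parameters plus the injected cumulative effect in g C m-2
#'   evaluated 1 and 2 years after rewetting).
#' @export
simulate_campaign <- function(seed = 1, start = "2019-10-01",
                              end = "2023-10-01", params = driver_params(),
                              truth = flux_truth_params(),
                              treatment = treatment_spec(),
                              gap_fraction = 0.3, n_wells = 5) {
  set.seed(seed)
  sites <- list()
  for (site in c("control", "treatment")) {
    trt <- if (site == "treatment") treatment else null_treatment()
    drv <- gen_drivers(params, start, end)
    fx <- gen_true_fluxes(drv, truth, trt, site_id = site)
    obs_co2 <- degrade(fx$co2$factual, gap_fraction)
    obs_ch4 <- degrade(fx$ch4$factual, gap_fraction)
    wells <- lapply(seq_len(n_wells), function(j) {
      halfhour_series(site, paste0("WTD_", j), drv$timestamp,
                      fx$wtd_factual$values + rnorm(1, 0, 3) +
                        rnorm(length(drv$timestamp), 0, 0.5), "cm")
    })
    names(wells) <- paste0("WTD_", seq_len(n_wells))
    sites[[site]] <- list(drivers = drv, fluxes = fx,
                          observed = list(co2 = obs_co2, ch4 = obs_ch4),
                          wells = wells)
  }
  # injected cumulative effect at the treatment site, from the noiseless truth
  fxt <- sites$treatment$fluxes
  ts <- sites$treatment$drivers$timestamp
  eff <- function(gas, prefix) {
    d <- fxt[[gas]]$mu_factual - fxt[[gas]]$mu_counterfactual
    cum <- cumsum(d * 1800 * MOLAR_MASS_C * prefix)
    at <- function(date) {
      d <- as.numeric(as.POSIXct(date, tz = "UTC"))
      i <- findInterval(d, as.numeric(ts))
      if (i < 1) 0 else if (d > max(as.numeric(ts))) NA_real_ else cum[i]
    }
    c(one_year = at(treatment$rewet_date + 365 * 86400),
      two_year = at(treatment$rewet_date + 731 * 86400))
  }
  list(sites = sites,
       truth = list(seed = seed, params = params, flux = truth,
                    treatment = treatment, gap_fraction = gap_fraction,
                    effect_gC = list(co2 = eff("co2", 1e-6),
                                     ch4 = eff("ch4", 1e-9))))
}
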