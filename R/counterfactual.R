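# Counterfactual flux modelling: period-specific BART ensembles per site
# and gas, counterfactual forcing of the pre-treatment model with
# treatment-period drivers, cumulative curves with uncertainty, and the
# rewetting-effect estimate.

#' Pre-treatment / treatment period boundaries
#'
#' The two contiguous, non-overlapping modelling periods, split at the
#' rewetting date: pre-treatment `[start, rewet)` and treatment
#' `[rewet, end)`.
#'
#' @param start,rewet,end instants (UTC); defaults are the study periods
#'   1 Oct 2019 / 1 Oct 2021 / 1 Oct 2023.
#' @return An object of class `"period_spec"`.
#' @export
period_spec <- function(start = "2019-10-01", rewet = rewetting_date(),
                        end = "2023-10-01") {
  start <- as.POSIXct(start, tz = "UTC")
  rewet <- as.POSIXct(rewet, tz = "UTC")
  end <- as.POSIXct(end, tz = "UTC")
  stopifnot(start < rewet, rewet < end)
  structure(list(pre = c(start, rewet), treatment = c(rewet, end)),
            class = "period_spec")
}

in_period <- function(ts, bounds) ts > bounds[1] & ts <= bounds[2]

guard_wtd <- function(features) {
  bad <- grepl("^WTD", features, ignore.case = TRUE)
  if (any(bad))
    stop("water table depth must not be a model predictor (it is the ",
         "treatment pathway; the pre-treatment model could not predict ",
         "counterfactual fluxes with it): remove ",
         paste(features[bad], collapse = ", "))
  invisible(features)
}

#' Train the period-specific flux models for one site and gas
#'
#' Fits two independent [bart()] ensembles: one on the quality-retained
#' flux records of the pre-treatment period, one on those of the
#' treatment period. Training rows are restricted to each period; gap
#' records are dropped. Water table depth is rejected as a predictor by a
#' configuration guard.
#'
#' @param flux a [halfhour_series()] of the gas (gaps allowed; they are
#'   excluded from training).
#' @param drivers data frame with `timestamp` and the feature columns
#'   (see [driver_features()]), gap-free.
#' @param periods a [period_spec()].
#' @param features feature names to use (default [driver_features()]).
#' @param min_records minimum valid records per period (default 500).
#' @param seed integer seed; the two fits use `seed` and `seed + 1`.
#' @param ... passed to [bart()] (e.g. `m`, `n_burn`, `n_draws`).
#' @return list with `pre_model` and `treatment_model` (class
#'   `"period_models"`), plus the gas label and units.
#' @export
train_period_models <- function(flux, drivers, periods = period_spec(),
                                features = driver_features(),
                                min_records = 500, seed = 1, ...) {
  stopifnot(inherits(flux, "halfhour_series"),
            inherits(periods, "period_spec"))
  guard_wtd(features)
  miss <- setdiff(features, names(drivers))
  if (length(miss)) stop("drivers lack features: ", paste(miss, collapse = ", "))
  ix <- match(as.numeric(flux$timestamps), as.numeric(drivers$timestamp))
  if (anyNA(ix)) stop("flux timestamps missing from the driver table")
  X <- drivers[ix, features, drop = FALSE]

  fit_one <- function(bounds, sd) {
    rows <- in_period(flux$timestamps, bounds) & !flux$gap_mask
    if (sum(rows) < min_records)
      stop("only ", sum(rows), " valid records in period ",
           format(bounds[1], "%Y-%m-%d"), "..", format(bounds[2], "%Y-%m-%d"),
           "; need ", min_records)
    bart(X[rows, , drop = FALSE], flux$values[rows], seed = sd, ...)
  }
  structure(list(
    pre_model = fit_one(periods$pre, seed),
    treatment_model = fit_one(periods$treatment, seed + 1),
    gas = flux$variable, units = flux$units, site_id = flux$site_id,
    periods = periods
  ), class = "period_models")
}

#' Actual and counterfactual flux draws over the treatment period
#'
#' Forces both period models with the treatment-period drivers. The
#' "actual" series is the treatment model's posterior draws (the model
#' estimates replace measurements everywhere, for consistency between the
#' actual and counterfactual sides); the "counterfactual" series is the
#' pre-treatment model forced with the same drivers.
#'
#' @param models a [train_period_models()] result.
#' @param drivers treatment-period driver table (`timestamp` + features),
#'   gap-free.
#' @return An object of class `"cf_draws"`: list with `timestamps`,
#'   `actual` and `counterfactual` (each an n-by-draws matrix), `gas`,
#'   `units`.
#' @export
predict_actual_and_counterfactual <- function(models, drivers) {
  stopifnot(inherits(models, "period_models"))
  if (nrow(drivers) == 0) stop("empty driver table")
  feats <- models$pre_model$features
  X <- drivers[, feats, drop = FALSE]
  if (anyNA(X)) stop("driver gaps in the treatment period; gap-fill first")
  structure(list(
    timestamps = drivers$timestamp,
    actual = predict(models$treatment_model, X, type = "draws"),
    counterfactual = predict(models$pre_model, X, type = "draws"),
    gas = models$gas, units = models$units, site_id = models$site_id
  ), class = "cf_draws")
}

# per-draw cumulative carbon curves (g C m-2) from a flux draw matrix
cumulate_draws <- function(draws, units) {
  prefix <- if (units == "umol m-2 s-1") 1e-6 else if (units == "nmol m-2 s-1")
    1e-9 else stop("flux units required, got '", units, "'")
  apply(draws, 2, cumsum) * 1800 * MOLAR_MASS_C * prefix
}

#' Rewetting-effect estimate from paired draw series
#'
#' Accumulates both draw ensembles to g C m-2 and takes, at each
#' evaluation date, the difference of the posterior-mean cumulative
#' fluxes: positive values mean the rewetting increased emission. The two
#' models are fit independently, so their draws are not paired; the
#' uncertainty half-width at each date combines the two curves' 5th-95th
#' percentile half-widths in quadrature. The draw-level difference
#' distribution (index pairing, arbitrary) is retained as well.
#'
#' @param cf a [predict_actual_and_counterfactual()] result.
#' @param eval_dates evaluation instants (default 1 and 2 years after the
#'   rewetting: 1 Oct 2022 and 1 Oct 2023).
#' @return An object of class `"effect_estimate"`: data frame `effects`
#'   (date, effect, halfwidth, p5, p95, actual and counterfactual
#'   cumulative means), plus the component curves and the retained
#'   difference draws.
#' @export
effect_estimate <- function(cf, eval_dates = c("2022-10-01", "2023-10-01")) {
  stopifnot(inherits(cf, "cf_draws"))
  eval_dates <- as.POSIXct(eval_dates, tz = "UTC")
  ts_num <- as.numeric(cf$timestamps)
  idx <- findInterval(as.numeric(eval_dates), ts_num)
  if (any(idx < 1) || any(as.numeric(eval_dates) > max(ts_num)))
    stop("evaluation date outside the treatment period")
  cum_a <- cumulate_draws(cf$actual, cf$units)
  cum_c <- cumulate_draws(cf$counterfactual, cf$units)

  row_summ <- function(m, i) {
    q <- quantile(m[i, ], c(0.05, 0.95), names = FALSE, type = 7)
    c(mean = mean(m[i, ]), p5 = q[1], p95 = q[2])
  }
  eff <- do.call(rbind, lapply(seq_along(idx), function(j) {
    i <- idx[j]
    a <- row_summ(cum_a, i)
    c_ <- row_summ(cum_c, i)
    hw <- combine_halfwidths((a["p95"] - a["p5"]) / 2,
                             (c_["p95"] - c_["p5"]) / 2)
    data.frame(date = eval_dates[j],
               effect = unname(a["mean"] - c_["mean"]),
               halfwidth = hw,
               p5 = unname(a["mean"] - c_["mean"]) - hw,
               p95 = unname(a["mean"] - c_["mean"]) + hw,
               actual_cum = unname(a["mean"]),
               counterfactual_cum = unname(c_["mean"]))
  }))
  structure(list(gas = cf$gas, site_id = cf$site_id, effects = eff,
                 cum_actual = cum_a, cum_counterfactual = cum_c,
                 diff_draws = cum_a[idx, , drop = FALSE] -
                   cum_c[idx, , drop = FALSE],
                 timestamps = cf$timestamps),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("Rewetting effect, %s at %s (g C m-2):\n", x$gas, x$site_id))
  e <- x$effects
  for (i in seq_len(nrow(e)))
    cat(sprintf("  %s: %+.1f +/- %.2g  (actual %.1f, counterfactual %.1f)\n",
                format(e$date[i], "%Y-%m-%d"), e$effect[i], e$halfwidth[i],
                e$actual_cum[i], e$counterfactual_cum[i]))
  invisible(x)
}

#' Combine two interval half-widths in quadrature
#'
#' The actual and counterfactual models are fitted independently, so
#' their uncertainty half-widths add in quadrature:
#' `sqrt(h1^2 + h2^2)`.
#'
#' @param h1,h2 non-negative half-widths.
#' @return the combined half-width.
#' @export
combine_halfwidths <- function(h1, h2) sqrt(h1^2 + h2^2)

#' Control-site validation of the counterfactual design
#'
#' At a site with no intervention, the pre-treatment model's simulation
#' of the treatment period should match the treatment model's estimate of
#' the actual fluxes. Reports, at each evaluation date, the cumulative
#' difference and whether the treatment-model estimate falls inside the
#' pre-treatment model's 5th-95th percentile band.
#'
#' @param models a [train_period_models()] fit on the control site.
#' @param drivers treatment-period driver table.
#' @param eval_dates evaluation instants.
#' @return data frame with `date`, `actual_cum`, `predicted_cum` (pre
#'   model), `p5`, `p95` (pre-model band) and `inside_band`.
#' @export
control_validation <- function(models, drivers,
                               eval_dates = c("2022-10-01", "2023-10-01")) {
  cf <- predict_actual_and_counterfactual(models, drivers)
  eval_dates <- as.POSIXct(eval_dates, tz = "UTC")
  idx <- findInterval(as.numeric(eval_dates), as.numeric(cf$timestamps))
  stopifnot(all(idx >= 1))
  cum_a <- cumulate_draws(cf$actual, cf$units)
  cum_c <- cumulate_draws(cf$counterfactual, cf$units)
  do.call(rbind, lapply(seq_along(idx), function(j) {
    i <- idx[j]
    q <- quantile(cum_c[i, ], c(0.05, 0.95), names = FALSE, type = 7)
    act <- mean(cum_a[i, ])
    data.frame(date = eval_dates[j], actual_cum = act,
               predicted_cum = mean(cum_c[i, ]), p5 = q[1], p95 = q[2],
               inside_band = act >= q[1] & act <= q[2])
  }))
}
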