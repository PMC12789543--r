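# Driver-matrix construction: reanalysis bias correction, tree-ensemble gap
# filling, and the derived features (growing degree days, time since rain,
# vapour pressure deficit).

#' Linear bias correction of a reanalysis series against onsite data
#'
#' Ordinary least squares of the onsite variable on the reanalysis
#' variable, fitted only where both are observed; the corrected series is
#' `slope * reanalysis + intercept` everywhere the reanalysis is
#' available.
#'
#' @param reanalysis,onsite numeric vectors on the same timestamps (`NA` =
#'   gap).
#' @param min_overlap minimum overlapping records required (default 100).
#' @return list with `slope`, `intercept`, `n`, `residual_sd` and
#'   `corrected` (numeric vector).
#' @export
linear_bias_correct <- function(reanalysis, onsite, min_overlap = 100) {
  ok <- !is.na(reanalysis) & !is.na(onsite)
  if (sum(ok) < min_overlap)
    stop("need at least ", min_overlap, " overlapping records, got ", sum(ok))
  if (sd(reanalysis[ok]) == 0)
    stop("reanalysis series has zero variance on the overlap")
  fit <- lm(onsite[ok] ~ reanalysis[ok])
  b <- unname(coef(fit))
  list(slope = b[2], intercept = b[1], n = sum(ok),
       residual_sd = sd(fit$residuals),
       corrected = b[2] * reanalysis + b[1])
}

#' Tree-ensemble gap filling
#'
#' Fills gaps in a target series with the posterior-mean prediction of the
#' package's own tree ensemble ([bart()]) trained on the observed records.
#' Observed records are never touched. Deterministic for a fixed seed.
#'
#' @param target numeric vector with `NA` gaps, or a [halfhour_series()].
#' @param predictors data frame or matrix of predictor columns, gap-free
#'   at least at the target's gap locations.
#' @param seed integer seed for the ensemble fit.
#' @param m,n_burn,n_draws,n_chains ensemble size and sampler lengths; the
#'   defaults are lighter than [bart()]'s since only the posterior mean is
#'   used.
#' @return the filled vector (or series), plus attribute `fill_fraction`.
#' @export
ensemble_gapfill <- function(target, predictors, seed = 1, m = 20,
                             n_burn = 100, n_draws = 50, n_chains = 2) {
  series <- NULL
  if (inherits(target, "halfhour_series")) {
    series <- target
    target <- series$values
  }
  predictors <- as.data.frame(predictors)
  stopifnot(nrow(predictors) == length(target))
  gaps <- is.na(target)
  if (!any(gaps)) {
    out <- target
  } else {
    bad <- gaps & apply(predictors, 1, anyNA)
    if (any(bad))
      stop("predictor gaps coincide with target gaps at rows: ",
           paste(head(which(bad), 5), collapse = ", "),
           if (sum(bad) > 5) " ..." else "")
    obs <- !gaps & !apply(predictors, 1, anyNA)
    fit <- bart(predictors[obs, , drop = FALSE], target[obs], m = m,
                n_burn = n_burn, n_draws = n_draws, n_chains = n_chains,
                seed = seed)
    out <- target
    out[gaps] <- predict(fit, predictors[gaps, , drop = FALSE], type = "mean")
  }
  attr(out, "fill_fraction") <- mean(gaps)
  if (!is.null(series)) {
    series$values <- as.numeric(out)
    series$gap_mask <- is.na(series$values)
    attr(series, "fill_fraction") <- mean(gaps)
    return(series)
  }
  out
}

#' Derived driver features
#'
#' Growing degree days (GDD): cumulative sum of `max(0, daily mean TA -
#' t_base)` from 1 January, base 5 degC, resetting at each calendar year
#' boundary; every half-hour of a day carries that day's cumulative value.
#' Time since rain: hours since the last half-hour with precipitation of
#' at least `rain_threshold` mm (hours since series start before the first
#' event). Vapour pressure deficit from temperature and relative humidity
#' by the Magnus saturation formula.
#'
#' @param timestamps `POSIXct` half-hour stamps (interval ends, UTC).
#' @param ta air temperature, degC, gap-free.
#' @param precip precipitation, mm per half-hour, gap-free.
#' @param rh optional relative humidity (percent) for the VPD output.
#' @param t_base GDD base temperature, degC.
#' @param rain_threshold precipitation (mm per half-hour) that resets the
#'   dry clock.
#' @return data frame with `GDD` (degC day), `TSR` (h) and, when `rh` is
#'   given, `VPD` (kPa).
#' @export
derive_features <- function(timestamps, ta, precip, rh = NULL, t_base = 5,
                            rain_threshold = 0.1) {
  stopifnot(!anyNA(ta), !anyNA(precip))
  day <- as.Date(timestamps - 900, tz = "UTC")  # day of the interval midpoint
  dmean <- tapply(ta, day, mean)
  dexc <- pmax(as.numeric(dmean) - t_base, 0)
  yr <- format(as.Date(names(dmean)), "%Y")
  gdd_daily <- as.numeric(unlist(lapply(split(dexc, yr), cumsum),
                                 use.names = FALSE))
  names(gdd_daily) <- names(dmean)
  gdd <- gdd_daily[as.character(day)]

  rain <- precip >= rain_threshold
  idx <- seq_along(precip)
  last_rain <- cummax(ifelse(rain, idx, 0L))
  tsr <- (idx - last_rain) * 0.5  # half-hours to hours

  out <- data.frame(GDD = unname(gdd), TSR = tsr)
  if (!is.null(rh)) {
    es <- 0.6112 * exp(17.62 * ta / (243.12 + ta))  # Magnus, kPa
    out$VPD <- es * (1 - rh / 100)
  }
  out
}

#' The driver feature columns used by the flux models
#'
#' The nine environmental variables expand to thirteen numeric features:
#' shortwave and longwave incoming radiation, air temperature and
#' pressure, vapour pressure deficit, wind speed, growing degree days,
#' time since rain, and soil temperature at five depths. Water table
#' depth is deliberately not among them (see [train_period_models()]).
#'
#' @return character vector of the thirteen feature names.
#' @export
driver_features <- function() {
  c("SW_IN", "LW_IN", "TA", "PA", "VPD", "WS", "GDD", "TSR",
    "TS_5", "TS_10", "TS_20", "TS_40", "TS_70")
}

#' Assemble the model driver matrix from a raw driver table
#'
#' Adds the derived features (GDD, time since rain) to a [gen_drivers()]
#' style table and returns the thirteen feature columns of
#' [driver_features()] plus the timestamp.
#'
#' @param drivers data frame with `timestamp`, the meteorological columns
#'   and `P_RAIN`.
#' @return data frame: `timestamp` plus the feature columns, gap-free.
#' @export
build_driver_matrix <- function(drivers) {
  need <- c("timestamp", "SW_IN", "LW_IN", "TA", "PA", "VPD", "WS", "P_RAIN",
            paste0("TS_", c(5, 10, 20, 40, 70)))
  miss <- setdiff(need, names(drivers))
  if (length(miss)) stop("driver table lacks columns: ",
                         paste(miss, collapse = ", "))
  feat <- derive_features(drivers$timestamp, drivers$TA, drivers$P_RAIN)
  out <- cbind(drivers[c("timestamp", setdiff(driver_features(),
                                              c("GDD", "TSR")))], feat)
  out[c("timestamp", driver_features())]
}
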