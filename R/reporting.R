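# Study-style summaries: annual/cumulative budget tables, growing-season
# detection from daily NEE, diurnal composites, and water-table summaries.

# centred running mean with shrinking windows at the edges
running_mean <- function(x, k) {
  n <- length(x)
  h <- floor(k / 2)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Growing-season bounds from daily NEE
#'
#' The growing season starts on the day the site transitions from CO2
#' source to CO2 sink and ends at the reverse transition. Operationally:
#' smooth the daily mean NEE with a centred 7-day running mean, find the
#' longest run of negative (sink) days, and report its first and last
#' day. Runs shorter than `min_run` days leave the season undefined.
#'
#' @param dates `Date` vector covering one calendar year.
#' @param daily_nee gap-filled daily mean NEE (umol m-2 s-1, positive =
#'   source).
#' @param smooth_days running-mean window (days).
#' @param min_run minimum sink-run length (days) to count as a season.
#' @param midsummer a day the season must contain (default 1 July of the
#'   data's year); this anchors the rule to the summer sink period and
#'   keeps winter sink artefacts (e.g. in sign-flipped data) from
#'   qualifying.
#' @return list with `start`, `end` (`Date`, `NA` when absent) and
#'   `present`.
#' @export
growing_season_bounds <- function(dates, daily_nee, smooth_days = 7,
                                  min_run = 14, midsummer = NULL) {
  stopifnot(length(dates) == length(daily_nee), !anyNA(daily_nee))
  if (is.null(midsummer))
    midsummer <- as.Date(paste0(format(dates[1], "%Y"), "-07-01"))
  sm <- running_mean(daily_nee, smooth_days)
  r <- rle(sm < 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cand <- which(r$values & r$lengths >= min_run &
                  dates[starts] <= midsummer & dates[ends] >= midsummer)
  if (!length(cand))
    return(list(start = as.Date(NA), end = as.Date(NA), present = FALSE))
  best <- cand[which.max(r$lengths[cand])]
  list(start = dates[starts[best]], end = dates[ends[best]], present = TRUE)
}

#' Diurnal composite of a half-hourly series
#'
#' Mean flux per half-hour of day over retained (non-gap) records,
#' computed separately inside and outside the growing season.
#'
#' @param series a [halfhour_series()].
#' @param season optional [growing_season_bounds()] list; when absent or
#'   `present = FALSE` everything is "non-growing".
#' @return data frame with `hour` (0, 0.5, ..., 23.5), `growing` and
#'   `non_growing` mean fluxes (`NaN` where a bin has no records).
#' @export
diurnal_composite <- function(series, season = NULL) {
  stopifnot(inherits(series, "halfhour_series"))
  lt <- as.POSIXlt(series$timestamps - 900, tz = "UTC")
  hour <- lt$hour + floor(lt$min / 30) * 0.5
  d <- as.Date(series$timestamps - 900, tz = "UTC")
  in_season <- if (!is.null(season) && isTRUE(season$present))
    d >= season$start & d <= season$end else rep(FALSE, length(d))
  ok <- !series$gap_mask
  bins <- seq(0, 23.5, by = 0.5)
  comp <- function(sel) {
    vapply(bins, function(h) {
      i <- sel & ok & hour == h
      if (any(i)) mean(series$values[i]) else NaN
    }, numeric(1))
  }
  data.frame(hour = bins, growing = comp(in_season),
             non_growing = comp(!in_season))
}

#' Water-table summary over a period
#'
#' Median depth per well over the non-missing records of the period, then
#' the median across wells. Depth is in cm below the surface, positive
#' downward.
#'
#' @param wells named list of [halfhour_series()] (one per well).
#' @param period length-2 `POSIXct` (start, end]; `NULL` = whole series.
#' @return An object of class `"wtd_summary"`: list with `per_well`
#'   (named numeric) and `median` (cross-well median).
#' @export
wtd_summary <- function(wells, period = NULL) {
  stopifnot(length(wells) >= 1)
  per_well <- vapply(wells, function(w) {
    v <- w$values
    if (!is.null(period)) {
      sel <- in_period(w$timestamps, period)
      if (!any(sel)) stop("well ", w$variable, " has no records in period")
      v <- v[sel]
    }
    v <- v[!is.na(v)]
    if (length(v) == 0) stop("well ", w$variable, " has no non-missing records")
    median(v)
  }, numeric(1))
  structure(list(per_well = per_well, median = median(per_well)),
            class = "wtd_summary")
}

#' Water-table rise between two periods
#'
#' Reported as `before - after` in cm: positive means the water table
#' rose (got shallower).
#'
#' @param before,after [wtd_summary()] objects.
#' @return rise in cm.
#' @export
wtd_rise <- function(before, after) {
  stopifnot(inherits(before, "wtd_summary"), inherits(after, "wtd_summary"))
  before$median - after$median
}

#' Annual carbon budget table
#'
#' Lays out per-year fluxes as a campaign budget table: annual values
#' per site and gas, the multi-year cumulative total, the overall mean,
#' and (for a treated site) the means of the years before and after the
#' treatment boundary.
#'
#' @param annual data frame with columns `site`, `gas`, `year` (ordered
#'   labels) and `flux_gC` (g C m-2 yr-1).
#' @param n_before number of years before the treatment boundary (default
#'   2 of 4).
#' @return data frame with one row per site/gas: `cumulative_gC`,
#'   `mean_gC`, `mean_before_gC`, `mean_after_gC`.
#' @export
flux_budget_table <- function(annual, n_before = 2) {
  stopifnot(all(c("site", "gas", "year", "flux_gC") %in% names(annual)))
  groups <- unique(annual[c("site", "gas")])
  out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    g <- annual[annual$site == groups$site[i] & annual$gas == groups$gas[i], ]
    g <- g[order(g$year), ]
    v <- g$flux_gC
    data.frame(site = groups$site[i], gas = groups$gas[i],
               n_years = length(v),
               cumulative_gC = sum(v), mean_gC = mean(v),
               mean_before_gC = mean(v[seq_len(min(n_before, length(v)))]),
               mean_after_gC = if (length(v) > n_before)
                 mean(v[(n_before + 1):length(v)]) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
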