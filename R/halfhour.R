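#' Half-hourly flux or driver series
#'
#' The basic container for eddy-covariance work: a strictly increasing,
#' uniformly spaced 30-minute time series of one measured quantity at one
#' site, with an explicit gap mask. By convention each timestamp labels the
#' END of its 30-minute averaging interval. Fluxes carry units
#' `"umol m-2 s-1"` (CO2) or `"nmol m-2 s-1"` (CH4), positive for emission
#' from the surface to the atmosphere; drivers use SI labels.
#'
#' @param site_id site label, e.g. `"control"`.
#' @param variable variable label, e.g. `"NEE_CO2"`, `"F_CH4"`, `"TA"`.
#' @param timestamps `POSIXct` (UTC), strictly increasing at exact 30-min
#'   spacing.
#' @param values numeric; `NA` marks a gap.
#' @param units unit label; must be one of [flux_units()] or a recognised
#'   driver label.
#' @return An object of class `"halfhour_series"`.
#' @export
halfhour_series <- function(site_id, variable, timestamps, values, units) {
  timestamps <- as.POSIXct(timestamps, tz = "UTC")
  values <- as.numeric(values)
  if (length(timestamps) != length(values))
    stop("timestamps and values lengths differ")
  if (anyNA(timestamps)) stop("unparseable timestamps")
  d <- diff(as.numeric(timestamps))
  bad <- which(d != 1800)
  if (length(bad))
    stop("non-uniform 30-min spacing at ",
         format(timestamps[bad[1] + 1], "%Y-%m-%d %H:%M:%S", tz = "UTC"),
         " (interval of ", d[bad[1]], " s)")
  if (!units %in% known_units())
    stop("unknown units label '", units, "'; known: ",
         paste(known_units(), collapse = ", "))
  structure(list(site_id = site_id, variable = variable,
                 timestamps = timestamps, values = values,
                 gap_mask = is.na(values), units = units),
            class = "halfhour_series")
}

#' @export
print.halfhour_series <- function(x, ...) {
  cat(sprintf("<halfhour_series> %s / %s [%s]\n", x$site_id, x$variable,
              x$units))
  cat(sprintf("  %d records, %s .. %s, %.1f%% gaps\n", length(x$values),
              format(min(x$timestamps), tz = "UTC"),
              format(max(x$timestamps), tz = "UTC"),
              100 * mean(x$gap_mask)))
  invisible(x)
}

#' Flux unit labels
#'
#' Unit labels accepted for gas fluxes: micromoles (CO2) and nanomoles
#' (CH4) per square metre per second.
#' @return character vector of the two flux unit labels.
#' @export
flux_units <- function() c("umol m-2 s-1", "nmol m-2 s-1")

known_units <- function() {
  c(flux_units(), "W m-2", "degC", "K", "kPa", "hPa", "m s-1", "mm", "cm",
    "percent", "degC d", "h", "mm 30min-1", "dimensionless")
}

#' Read a half-hourly series from CSV
#'
#' Reads one column of a half-hourly CSV table into a [halfhour_series()].
#' Empty or `NA` cells become gaps. Spacing is validated; a non-uniform
#' step is a hard error naming the first offending timestamp.
#'
#' @param path CSV file path.
#' @param value_col name of the numeric column to read.
#' @param units unit label to record (the file itself is unit-less).
#' @param site_id,variable labels for the series; `variable` defaults to
#'   `value_col`.
#' @param timestamp_col name of the ISO-8601 timestamp column.
#' @return A [halfhour_series()].
#' @export
read_halfhour_csv <- function(path, value_col, units, site_id = "site",
                              variable = value_col,
                              timestamp_col = "timestamp") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!timestamp_col %in% names(df))
    stop("no timestamp column '", timestamp_col, "' in ", path)
  if (!value_col %in% names(df))
    stop("no column '", value_col, "' in ", path)
  ts <- as.POSIXct(df[[timestamp_col]], tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  vals <- suppressWarnings(as.numeric(df[[value_col]]))
  halfhour_series(site_id, variable, ts, vals, units)
}

#' Write a half-hourly series to CSV
#'
#' Inverse of [read_halfhour_csv()]: two columns, ISO-8601 timestamp and
#' value (gaps written as empty cells). Values round-trip bitwise via
#' full-precision formatting.
#'
#' @param series a [halfhour_series()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_halfhour_csv <- function(series, path) {
  df <- data.frame(
    timestamp = format(series$timestamps, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    value = sprintf("%.17g", series$values),
    stringsAsFactors = FALSE
  )
  names(df)[2] <- series$variable
  df[[2]][series$gap_mask] <- ""
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Hydrological years of the study calendar
#'
#' Annual carbon budgets are kept on hydrological years running 1 October
#' to 30 September, labelled `"YYYY/YY"`. The four study years are
#' `2019/20` to `2022/23`, and the rewetting boundary is 1 October 2021.
#'
#' @param labels character vector like `"2019/20"`; defaults to the four
#'   study years.
#' @return data frame with `label`, `start`, `end` (`POSIXct` UTC; `end`
#'   is the exclusive boundary, i.e. 1 October of the following year).
#' @export
hydro_years <- function(labels = c("2019/20", "2020/21", "2021/22",
                                   "2022/23")) {
  y1 <- as.integer(substr(labels, 1, 4))
  data.frame(
    label = labels,
    start = as.POSIXct(paste0(y1, "-10-01 00:00:00"), tz = "UTC"),
    end = as.POSIXct(paste0(y1 + 1, "-10-01 00:00:00"), tz = "UTC"),
    stringsAsFactors = FALSE
  )
}

#' The rewetting date used as the treatment boundary
#' @return `POSIXct` 2021-10-01 00:00 UTC.
#' @export
rewetting_date <- function() as.POSIXct("2021-10-01 00:00:00", tz = "UTC")

# molar mass of carbon, g / mol (CODATA)
MOLAR_MASS_C <- 12.011

#' Integrate a gap-free flux series to cumulative carbon mass
#'
#' Converts a half-hourly CO2 or CH4 flux series (molar flux, positive =
#' emission) into a cumulative curve in g C per square metre: each record
#' contributes `value * 1800 s * 12.011 g/mol` at the appropriate molar
#' prefix (1e-6 for umol, 1e-9 for nmol). The curve starts at exactly 0 at
#' the start of the first averaging interval (30 minutes before the first
#' timestamp, which labels the interval end).
#'
#' @param series a gap-free flux [halfhour_series()] in one of
#'   [flux_units()].
#' @return An object of class `"cumulative_curve"`: list with `timestamps`
#'   (length n+1, beginning at the series start) and `cumulative_gC`.
#' @export
flux_to_carbon_mass <- function(series) {
  stopifnot(inherits(series, "halfhour_series"))
  if (!series$units %in% flux_units())
    stop("flux units must be one of: ", paste(flux_units(), collapse = ", "))
  if (any(series$gap_mask))
    stop("series contains ", sum(series$gap_mask),
         " gaps; gap-fill before integrating")
  prefix <- if (series$units == "umol m-2 s-1") 1e-6 else 1e-9
  inc <- series$values * 1800 * MOLAR_MASS_C * prefix
  structure(list(
    site_id = series$site_id, variable = series$variable,
    timestamps = c(series$timestamps[1] - 1800, series$timestamps),
    cumulative_gC = c(0, cumsum(inc))
  ), class = "cumulative_curve")
}

#' @export
print.cumulative_curve <- function(x, ...) {
  cat(sprintf("<cumulative_curve> %s / %s: %.2f g C m-2 over %s .. %s\n",
              x$site_id, x$variable, tail(x$cumulative_gC, 1),
              format(min(x$timestamps), tz = "UTC"),
              format(max(x$timestamps), tz = "UTC")))
  invisible(x)
}

# cumulative value at instant t (stepwise-constant between half-hour marks)
curve_value_at <- function(curve, t) {
  t <- as.POSIXct(t, tz = "UTC")
  idx <- findInterval(as.numeric(t), as.numeric(curve$timestamps))
  if (any(idx < 1) || any(t > max(curve$timestamps)))
    stop("instant outside the span of the cumulative curve")
  curve$cumulative_gC[idx]
}

#' Annual totals of a cumulative carbon curve
#'
#' Per-hydro-year increments of a cumulative curve, in g C per square
#' metre. Years must be fully covered by the curve; partial coverage is an
#' error (no pro-rating). The sum of the annual totals equals the
#' end-minus-start cumulative difference exactly.
#'
#' @param curve a [flux_to_carbon_mass()] result.
#' @param years a [hydro_years()] data frame.
#' @return data frame with `label` and `total_gC`.
#' @export
annual_totals <- function(curve, years = hydro_years()) {
  stopifnot(inherits(curve, "cumulative_curve"))
  lo <- min(curve$timestamps)
  hi <- max(curve$timestamps)
  miss <- years$start < lo | years$end > hi
  if (any(miss))
    stop("curve only partially covers year(s): ",
         paste(years$label[miss], collapse = ", "))
  data.frame(
    label = years$label,
    total_gC = curve_value_at(curve, years$end) -
      curve_value_at(curve, years$start),
    stringsAsFactors = FALSE
  )
}
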