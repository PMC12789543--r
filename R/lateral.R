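# Lateral dissolved-organic-carbon export: sampling-date mean
# concentrations, annual water-balance discharge, and the catchment
# export flux.

#' Catchment specification for the water balance
#'
#' @param site site label.
#' @param area_m2 catchment area, m2, `> 0`.
#' @param precip_mm,et_mm,storage_mm annual precipitation,
#'   evapotranspiration and storage change, mm.
#' @return An object of class `"catchment_spec"`.
#' @export
catchment_spec <- function(site, area_m2, precip_mm, et_mm,
                           storage_mm = 0) {
  if (area_m2 <= 0) stop("catchment area must be positive")
  structure(list(site = site, area_m2 = area_m2, precip_mm = precip_mm,
                 et_mm = et_mm, storage_mm = storage_mm),
            class = "catchment_spec")
}

#' Annual discharge from a bucket water balance
#'
#' The simplest annual water balance: discharge is the non-negative
#' residual of precipitation minus evapotranspiration minus storage
#' change, converted from mm over the catchment area to m3:
#' `Q = max(0, P - ET - dS) / 1000 * A`.
#'
#' @param catchment a [catchment_spec()].
#' @return discharge, m3 yr-1.
#' @export
annual_discharge <- function(catchment) {
  stopifnot(inherits(catchment, "catchment_spec"))
  max(0, catchment$precip_mm - catchment$et_mm - catchment$storage_mm) /
    1000 * catchment$area_m2
}

#' Lateral DOC export flux
#'
#' `DOC_f = Q * DOC_c / A`: discharge (m3 yr-1) times concentration
#' (g C m-3, numerically equal to mg l-1) over catchment area (m2),
#' giving g C m-2 yr-1.
#'
#' @param Q annual discharge, m3 yr-1.
#' @param doc_c DOC concentration, g C m-3.
#' @param area_m2 catchment area, m2.
#' @return DOC export, g C m-2 yr-1.
#' @export
doc_flux <- function(Q, doc_c, area_m2) {
  if (area_m2 == 0) stop("catchment area must be nonzero")
  stopifnot(Q >= 0, doc_c >= 0, area_m2 > 0)
  Q * doc_c / area_m2
}

#' Mean DOC concentration across sampling dates
#'
#' Arithmetic (flow-unweighted) mean of grab-sample concentrations, the
#' convention used for the annual export estimates.
#'
#' @param conc numeric vector of concentrations, mg l-1, all positive.
#' @return the mean concentration, mg l-1.
#' @export
mean_concentration <- function(conc) {
  if (length(conc) == 0) stop("no DOC samples")
  if (any(is.na(conc)) || any(conc <= 0))
    stop("DOC concentrations must be positive and non-missing")
  mean(conc)
}

#' Back-solve the catchment area implied by a (Q, DOC_c, DOC_f) triple
#'
#' Catchment areas are often not reported alongside export estimates;
#' inverting the export equation gives `A = Q * DOC_c / DOC_f`. Comparing
#' implied areas across years of the same catchment is a consistency
#' check: a drifting implied area means the concentrations were
#' flow-weighted or the discharge integration differed between years.
#'
#' @param Q discharge, m3 yr-1.
#' @param doc_c concentration, g C m-3.
#' @param doc_f export flux, g C m-2 yr-1.
#' @return implied area, m2.
#' @export
implied_catchment_area <- function(Q, doc_c, doc_f) {
  stopifnot(doc_f > 0)
  Q * doc_c / doc_f
}
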