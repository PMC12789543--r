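# 20 Hz raw-window processing: double rotation, block-average Reynolds
# covariance with constant lag compensation, WPL density correction for the
# open-path CH4 channel, Vickers-Mahrt raw-data screening, Foken-Wichura
# stationarity flagging, and record-level filtering.

#' Double rotation of a raw wind field
#'
#' Corrects anemometer tilt by two sequential rotations: a yaw rotation
#' zeroing the mean crosswind, then a pitch rotation zeroing the mean
#' vertical wind. Per-sample wind speed magnitude is preserved (the
#' rotations are isometries).
#'
#' @param window a `"raw_window"` (see [gen_raw_window()]).
#' @return list with `window` (rotated), `yaw`, `pitch` (radians).
#' @export
double_rotation <- function(window) {
  stopifnot(inherits(window, "raw_window"))
  ub <- mean(window$u); vb <- mean(window$v); wb <- mean(window$w)
  if (sqrt(ub^2 + vb^2 + wb^2) < 1e-12)
    stop("zero mean wind: window unusable for rotation")
  yaw <- atan2(vb, ub)
  u1 <- window$u * cos(yaw) + window$v * sin(yaw)
  v1 <- -window$u * sin(yaw) + window$v * cos(yaw)
  pitch <- atan2(wb, mean(u1))
  u2 <- u1 * cos(pitch) + window$w * sin(pitch)
  w2 <- -u1 * sin(pitch) + window$w * cos(pitch)
  out <- window
  out$u <- u2; out$v <- v1; out$w <- w2
  list(window = out, yaw = yaw, pitch = pitch)
}

# population covariance with block means removed once (no detrending)
block_cov <- function(a, b) mean((a - mean(a)) * (b - mean(b)))

#' Block-average Reynolds covariance flux
#'
#' The uncorrected kinematic flux: the covariance of the vertical wind
#' fluctuation with the scalar fluctuation over the 30-minute block, after
#' a single block-mean removal (no detrending), with an optional constant
#' time-lag compensation shifting the scalar channel.
#'
#' @param window a rotated `"raw_window"`.
#' @param channel scalar channel name (`"ch4"`, `"co2"`, `"h2o"`, `"ts"`).
#' @param lag_samples constant lag in samples; positive means the scalar
#'   lags the wind. Must be below a tenth of the window length.
#' @return the covariance flux (scalar units times m s-1).
#' @export
block_covariance_flux <- function(window, channel = "ch4", lag_samples = 0) {
  stopifnot(inherits(window, "raw_window"))
  c_ <- window[[channel]]
  w <- window$w
  n <- length(w)
  if (abs(lag_samples) >= n / 10)
    stop("lag of ", lag_samples, " samples exceeds a tenth of the window")
  if (lag_samples > 0) {
    w <- w[1:(n - lag_samples)]
    c_ <- c_[(1 + lag_samples):n]
  } else if (lag_samples < 0) {
    k <- -lag_samples
    w <- w[(1 + k):n]
    c_ <- c_[1:(n - k)]
  }
  block_cov(w, c_)
}

#' Webb-Pearman-Leuning density correction for open-path CH4
#'
#' Standard open-path WPL form: the corrected flux is
#' \deqn{F = F_0 + \mu \frac{\rho_m}{\rho_d} E +
#'   (1 + \mu\sigma)\frac{\rho_m}{\bar T}\frac{H}{\rho c_p}}
#' with \eqn{\mu} the ratio of dry-air to water molar masses and
#' \eqn{\sigma = \rho_v/\rho_d}. The gas-amount unit cancels: `raw_flux`
#' and `rho_m` just need the same basis (e.g. nmol m-2 s-1 with
#' nmol m-3).
#'
#' @param raw_flux uncorrected CH4 flux (e.g. nmol m-2 s-1).
#' @param H_cov sensible heat flux, W m-2.
#' @param E_cov water vapour mass flux, kg m-2 s-1.
#' @param air list with `T_k` (mean air temperature, K), `rho_d` (dry air
#'   density, kg m-3), `rho_v` (vapour density, kg m-3), `rho_m` (mean CH4
#'   density, same amount basis as `raw_flux`, per m-3).
#' @return corrected CH4 flux, same units as `raw_flux`.
#' @export
wpl_ch4 <- function(raw_flux, H_cov, E_cov, air) {
  stopifnot(all(c("T_k", "rho_d", "rho_v", "rho_m") %in% names(air)))
  if (air$rho_d <= 0 || air$rho_v < 0 || air$rho_m <= 0 || air$T_k <= 0)
    stop("nonphysical air state (densities and temperature must be positive)")
  mu <- 28.9647 / 18.01528
  sigma <- air$rho_v / air$rho_d
  cp <- 1005
  rho_a <- air$rho_d + air$rho_v
  raw_flux + mu * (air$rho_m / air$rho_d) * E_cov +
    (1 + mu * sigma) * (air$rho_m / air$T_k) * (H_cov / (rho_a * cp))
}

#' Default Vickers-Mahrt screening thresholds
#'
#' The 1997 defaults: spikes are points beyond 3.5 local (5-minute moving
#' window) standard deviations in runs of at most 3 consecutive samples,
#' hard-flagging the record when more than 1% of samples are spikes;
#' dropouts are runs stuck in one bin of the empirical distribution for
#' more than 10% of the record; amplitude resolution fails when over 70%
#' of 100 histogram bins across mean +/- 3.5 sd are empty; |skewness| > 2
#' or kurtosis outside [1, 8] hard-flags; a Haar half-window mean
#' difference above 3 total standard deviations flags a discontinuity;
#' and fixed absolute limits per channel.
#'
#' @param ... overrides of the default elements.
#' @return list of thresholds used by [vickers_mahrt()].
#' @export
vm_config <- function(...) {
  cfg <- list(
    spike_sd = 3.5, spike_win = 6000, spike_max_run = 3,
    spike_hard_frac = 0.01,
    dropout_bins = 100, dropout_frac = 0.10,
    amp_bins = 100, amp_empty_frac = 0.7,
    skew_lim = 2, kurt_lim = c(1, 8),
    haar_win = 6000, haar_step = 1200, haar_thresh = 3,
    abs_limits = list(u = c(-30, 30), v = c(-30, 30), w = c(-10, 10),
                      ts = c(243, 323), co2 = c(200, 900), h2o = c(0, 40),
                      ch4 = c(0, 1))
  )
  utils::modifyList(cfg, list(...))
}

moving_stats <- function(x, win) {
  n <- length(x)
  h <- floor(win / 2)
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  m <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  v <- (cs2[hi + 1] - cs2[lo]) / (hi - lo + 1) - m^2
  list(mean = m, sd = sqrt(pmax(v, 0)))
}

vm_channel <- function(x, name, cfg) {
  n <- length(x)
  if (all(is.na(x))) {
    return(data.frame(channel = name,
                      test = c("spikes", "dropouts", "abs_limits",
                               "amplitude", "skewness", "kurtosis", "haar"),
                      statistic = NA_real_, pass = FALSE))
  }
  xm <- mean(x); xs <- sd(x)

  # spikes: local 3.5-sd exceedances in runs of <= 3 consecutive samples
  ms <- moving_stats(x, cfg$spike_win)
  out <- abs(x - ms$mean) > cfg$spike_sd * pmax(ms$sd, 1e-12)
  r <- rle(out)
  spike_count <- sum(r$lengths[r$values & r$lengths <= cfg$spike_max_run])
  spike_frac <- spike_count / n

  # dropouts: longest run stuck in one distribution bin
  if (xs > 0) {
    bins <- cut(x, breaks = seq(min(x), max(x), length.out = cfg$dropout_bins + 1),
                include.lowest = TRUE, labels = FALSE)
    dropout_frac <- max(rle(bins)$lengths) / n
  } else dropout_frac <- 1

  # absolute limits
  lim <- cfg$abs_limits[[name]]
  abs_viol <- if (is.null(lim)) 0 else sum(x < lim[1] | x > lim[2])

  # amplitude resolution: empty-bin fraction over mean +/- 3.5 sd
  if (xs > 0) {
    br <- seq(xm - 3.5 * xs, xm + 3.5 * xs, length.out = cfg$amp_bins + 1)
    counts <- tabulate(cut(pmin(pmax(x, br[1]), br[length(br)]), br,
                           include.lowest = TRUE, labels = FALSE),
                       nbins = cfg$amp_bins)
    amp_empty <- mean(counts == 0)
  } else amp_empty <- 1

  z <- if (xs > 0) (x - xm) / xs else rep(0, n)
  skew <- mean(z^3)
  kurt <- mean(z^4)

  # Haar discontinuity: max half-window mean difference over total sd
  haar <- 0
  if (xs > 0) {
    h <- floor(cfg$haar_win / 2)
    starts <- seq(1, n - 2 * h + 1, by = cfg$haar_step)
    cs <- cumsum(c(0, x))
    m1 <- (cs[starts + h] - cs[starts]) / h
    m2 <- (cs[starts + 2 * h] - cs[starts + h]) / h
    haar <- max(abs(m2 - m1)) / xs
  }

  data.frame(
    channel = name,
    test = c("spikes", "dropouts", "abs_limits", "amplitude", "skewness",
             "kurtosis", "haar"),
    statistic = c(spike_frac, dropout_frac, abs_viol, amp_empty, skew, kurt,
                  haar),
    pass = c(spike_frac <= cfg$spike_hard_frac,
             dropout_frac <= cfg$dropout_frac,
             abs_viol == 0,
             amp_empty <= cfg$amp_empty_frac,
             abs(skew) <= cfg$skew_lim,
             kurt >= cfg$kurt_lim[1] & kurt <= cfg$kurt_lim[2],
             haar <= cfg$haar_thresh)
  )
}

#' Vickers-Mahrt raw-data screening battery
#'
#' Runs the spike, dropout, absolute-limit, amplitude-resolution,
#' skewness/kurtosis and Haar-discontinuity tests on the raw
#' (pre-rotation) channels of a window. An all-NA channel fails
#' everything.
#'
#' @param window a `"raw_window"`.
#' @param cfg thresholds from [vm_config()].
#' @param channels channels to screen.
#' @return An object of class `"vm_report"`: data frame of per-channel,
#'   per-test statistics and pass flags, with attribute `hard_fail`.
#' @export
vickers_mahrt <- function(window, cfg = vm_config(),
                          channels = c("u", "v", "w", "ts", "co2", "h2o",
                                       "ch4")) {
  stopifnot(inherits(window, "raw_window"))
  res <- do.call(rbind, lapply(channels, function(ch)
    vm_channel(window[[ch]], ch, cfg)))
  structure(res, hard_fail = any(!res$pass), class = c("vm_report",
                                                       "data.frame"))
}

#' Foken-Wichura stationarity flag
#'
#' Compares the 30-minute block covariance with the mean of the six
#' 5-minute sub-block covariances:
#' `RN_cov = |cov30 - mean(cov5)| / |cov30| * 100`. Flag 0 when
#' `RN_cov < 30`, 1 when `< 100`, else 2. A zero block covariance gets
#' flag 2 with `RN_cov = Inf`.
#'
#' @param window a rotated `"raw_window"`.
#' @param channel scalar channel used for the covariance.
#' @return list with `rn_cov` (percent) and `flag` (0, 1 or 2).
#' @export
foken_wichura <- function(window, channel = "ch4") {
  stopifnot(inherits(window, "raw_window"))
  w <- window$w
  c_ <- window[[channel]]
  n <- length(w)
  cov30 <- block_cov(w, c_)
  idx <- split(seq_len(n), ceiling(seq_len(n) / (n / 6)))
  cov5 <- vapply(idx, function(i) block_cov(w[i], c_[i]), numeric(1))
  if (cov30 == 0) return(list(rn_cov = Inf, flag = 2L))
  rn <- abs(cov30 - mean(cov5)) / abs(cov30) * 100
  list(rn_cov = rn, flag = if (rn < 30) 0L else if (rn < 100) 1L else 2L)
}

#' Process one raw window into a quality-flagged flux estimate
#'
#' The full record pipeline: Vickers-Mahrt screening on the raw channels,
#' double rotation, Foken-Wichura stationarity flagging, and the
#' block-average covariance flux with optional constant lag, plus the heat
#' and vapour covariance proxies and the mean horizontal wind speed. A
#' multiplicative spectral correction factor hook (default 1) is applied
#' to the flux.
#'
#' @param window a `"raw_window"`.
#' @param channel scalar channel to turn into a flux.
#' @param lag_samples constant lag compensation (samples).
#' @param cfg a [vm_config()].
#' @param spectral_factor multiplicative high/low-pass correction factor.
#' @return An object of class `"flux_estimate"`: list with `flux`,
#'   `wind_speed`, `fw_flag`, `rn_cov`, `vm_pass`, `H_proxy`, `E_proxy`,
#'   `vm_report`, rotation angles.
#' @export
process_raw_window <- function(window, channel = "ch4", lag_samples = 0,
                               cfg = vm_config(), spectral_factor = 1) {
  vm <- vickers_mahrt(window, cfg)
  wind_speed <- sqrt(mean(window$u)^2 + mean(window$v)^2)
  rot <- double_rotation(window)
  fw <- foken_wichura(rot$window, channel)
  flux <- block_covariance_flux(rot$window, channel, lag_samples) *
    spectral_factor
  structure(list(
    gas = channel, flux = flux, wind_speed = wind_speed,
    fw_flag = fw$flag, rn_cov = fw$rn_cov,
    vm_pass = !attr(vm, "hard_fail"), vm_report = vm,
    H_proxy = block_covariance_flux(rot$window, "ts"),
    E_proxy = block_covariance_flux(rot$window, "h2o"),
    yaw = rot$yaw, pitch = rot$pitch
  ), class = "flux_estimate")
}

#' Filter flux estimates on quality
#'
#' Retains only records with stationarity flag 0, mean horizontal wind of
#' at least `min_wind` (default 1.5 m s-1), and a clean Vickers-Mahrt
#' screen. Discards are returned with their reasons. The filter is
#' idempotent and record-order independent.
#'
#' @param estimates list of `"flux_estimate"` objects.
#' @param min_wind minimum mean horizontal wind speed, m s-1.
#' @return list with `retained` (list of estimates) and `discarded`
#'   (data frame of indices and comma-joined reasons).
#' @export
filter_fluxes <- function(estimates, min_wind = 1.5) {
  if (inherits(estimates, "flux_estimate")) estimates <- list(estimates)
  reasons <- lapply(estimates, function(e) {
    r <- character(0)
    if (e$wind_speed < min_wind) r <- c(r, "wind")
    if (e$fw_flag > 0) r <- c(r, "stationarity")
    if (!e$vm_pass) r <- c(r, "vm")
    r
  })
  keep <- lengths(reasons) == 0
  list(
    retained = estimates[keep],
    discarded = data.frame(
      index = which(!keep),
      reason = vapply(reasons[!keep], paste, character(1), collapse = ","),
      stringsAsFactors = FALSE
    )
  )
}
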