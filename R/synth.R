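#' Specification for synthetic gridded daily weather
#'
#' Describes a synthetic daily Tmin/Tmax cube with a north-south
#' temperature gradient, sinusoidal seasonality peaking in mid-July
#' (day 196 by default), a fixed diurnal range, and optional Gaussian
#' noise. The generator emulates the broad structure of mid-latitude
#' gridded temperature products (cooling northward, summer peak) without
#' attempting their spatial covariance or topography.
#'
#' The daily mean temperature of the cell in row `r` counted from the
#' south edge (`r = 0` at the south) on day `d` is
#' `base_mean - lat_gradient * r - seasonal_amplitude * (1 - cos(2 * pi *
#' (d - peak_day) / 365)) + noise`, so `base_mean` is the warmest-day mean
#' at the south edge and the seasonal swing is twice
#' `seasonal_amplitude`. Tmin/Tmax sit half the diurnal range below/above
#' the mean.
#'
#' @param n_rows,n_cols Grid size (row 1 of the stored grids = north).
#' @param n_days Number of days, starting at `start_date`.
#' @param base_mean Daily mean temperature (C) at the south edge on the
#'   warmest day.
#' @param lat_gradient Cooling per row moving north, degrees C.
#' @param seasonal_amplitude Seasonal half-swing, degrees C.
#' @param diurnal_range Tmax - Tmin, degrees C.
#' @param noise_sd SD of i.i.d. Gaussian noise added to the daily mean.
#' @param seed Integer seed making the cube reproducible.
#' @param start_date First calendar day.
#' @param peak_day Day of year of the seasonal peak.
#' @param geo A [grid_geometry()].
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(n_rows = 20L, n_cols = 20L, n_days = 365L,
                       base_mean = 35, lat_gradient = 1.5,
                       seasonal_amplitude = 12, diurnal_range = 10,
                       noise_sd = 0, seed = 1L,
                       start_date = as.Date("2018-01-01"),
                       peak_day = 196L,
                       geo = grid_geometry(xmin = -100, ymax = 45,
                                           xres = 0.1, yres = 0.1)) {
  stopifnot(n_rows >= 1L, n_cols >= 1L, n_days >= 1L,
            diurnal_range >= 0, noise_sd >= 0)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 n_days = as.integer(n_days), base_mean = base_mean,
                 lat_gradient = lat_gradient,
                 seasonal_amplitude = seasonal_amplitude,
                 diurnal_range = diurnal_range, noise_sd = noise_sd,
                 seed = as.integer(seed), start_date = as.Date(start_date),
                 peak_day = as.integer(peak_day), geo = geo),
            class = "synth_spec")
}

#' Generate a synthetic weather cube
#'
#' Deterministic per seed: the same `synth_spec` always yields the same
#' cube. With `noise_sd = 0`, `lat_gradient = 0` and
#' `seasonal_amplitude = 0` the cube is constant in space and time, which
#' drives the closed-form engine tests.
#'
#' @param spec A [synth_spec()].
#' @return A [weather_cube()].
#' @examples
#' cube <- generate_weather(synth_spec(n_rows = 2, n_cols = 2, n_days = 10,
#'                                     seasonal_amplitude = 0,
#'                                     lat_gradient = 0, base_mean = 20))
#' cube$tmax[1, 1, 1] - cube$tmin[1, 1, 1]  # the diurnal range
#' @export
generate_weather <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  dates <- seq(spec$start_date, by = 1, length.out = spec$n_days)
  doy <- as.POSIXlt(dates)$yday + 1
  season <- -spec$seasonal_amplitude *
    (1 - cos(2 * pi * (doy - spec$peak_day) / 365))
  # row 1 is the north edge: r rows from the south edge = n_rows - i
  r_from_south <- spec$n_rows - seq_len(spec$n_rows)
  lat <- spec$base_mean - spec$lat_gradient * r_from_south

  mean_td <- outer(lat, season, `+`)  # rows x days
  arr <- array(rep(mean_td, each = 1), c(spec$n_rows, spec$n_days))
  m <- array(NA_real_, c(spec$n_rows, spec$n_cols, spec$n_days))
  for (j in seq_len(spec$n_cols)) m[, j, ] <- arr
  if (spec$noise_sd > 0) {
    old <- .Random.seed_exists()
    set.seed(spec$seed)
    m <- m + array(stats::rnorm(length(m), 0, spec$noise_sd), dim(m))
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  weather_cube(dates,
               tmin = m - spec$diurnal_range / 2,
               tmax = m + spec$diurnal_range / 2,
               geo = spec$geo)
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  else NULL
}

#' Mean-preserving monthly-to-daily temperature interpolation
#'
#' Downscales 12 monthly mean temperatures to a smooth daily series whose
#' monthly averages reproduce the inputs. Daily values are first linearly
#' interpolated between month-midpoint anchors (wrapping December and
#' January cyclically), then corrected iteratively: each pass computes
#' the residual between the target and realized monthly means and adds a
#' smooth (midpoint-interpolated) correction curve, until every monthly
#' mean matches within `tol`.
#'
#' @param monthly_means Numeric vector of 12 monthly mean temperatures.
#' @param year Calendar year (decides February's length).
#' @param tol Convergence tolerance on each monthly mean, degrees C.
#' @param max_iter Iteration cap; exceeding it is an error reporting the
#'   residual.
#' @return Numeric vector of daily values (365 or 366).
#' @examples
#' mm <- 10 - 12 * cos(2 * pi * (1:12 - 0.5) / 12)
#' daily <- monthly_to_daily(mm, 2018)
#' tapply(daily, rep(1:12, times = c(31,28,31,30,31,30,31,31,30,31,30,31)),
#'        mean) - mm  # all within 0.01
#' @export
monthly_to_daily <- function(monthly_means, year = 2018L, tol = 0.01,
                             max_iter = 100L) {
  if (length(monthly_means) != 12L || !all(is.finite(monthly_means)))
    stop("monthly_means must be 12 finite values", call. = FALSE)
  mlen <- .month_lengths(year)
  ndays <- sum(mlen)
  month_of <- rep(seq_len(12L), times = mlen)
  ends <- cumsum(mlen)
  mids <- ends - (mlen - 1) / 2  # day number of each month's midpoint

  interp_cyclic <- function(anchors) {
    x <- c(mids[12L] - ndays, mids, mids[1L] + ndays)
    y <- c(anchors[12L], anchors, anchors[1L])
    stats::approx(x, y, xout = seq_len(ndays))$y
  }

  daily <- interp_cyclic(monthly_means)
  for (it in seq_len(max_iter)) {
    realized <- as.numeric(tapply(daily, month_of, mean))
    resid <- monthly_means - realized
    if (max(abs(resid)) <= tol) return(daily)
    daily <- daily + interp_cyclic(resid)
  }
  stop(sprintf(
    "monthly-to-daily interpolation did not converge (max residual %.4f C)",
    max(abs(monthly_means - as.numeric(tapply(daily, month_of, mean))))),
    call. = FALSE)
}

.month_lengths <- function(year) {
  leap <- (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
  c(31L, if (leap) 29L else 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L,
    30L, 31L)
}
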