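#' Parameters of the synthetic daily-temperature generator
#'
#' The generator emulates a station record of daily mean near-surface
#' temperature: an annual harmonic seasonal cycle plus an AR(1) residual.
#' `daily_sd` is the marginal standard deviation of the residual (the
#' innovation variance is scaled by `1 - ar1_coef^2` so the marginal
#' spread does not depend on the autocorrelation).
#'
#' @param mean_temp annual mean temperature (degrees C).
#' @param seasonal_amplitude amplitude of the annual cycle (degrees C).
#' @param phase phase of the annual harmonic (radians); the cycle peaks at
#'   day-of-year `365.25 * phase / (2 * pi)`.
#' @param ar1_coef lag-1 autocorrelation of the residual, in (-1, 1).
#' @param daily_sd marginal SD of the residual (degrees C), >= 0.
#' @param start_date,end_date ISO dates delimiting the series (inclusive).
#' @return an object of class `climate_params`.
#' @export
climate_params <- function(mean_temp = 14,
                           seasonal_amplitude = 8,
                           phase = 2 * pi * 197 / 365.25,
                           ar1_coef = 0.7,
                           daily_sd = 3,
                           start_date = "2000-01-01",
                           end_date = "2014-12-31") {
  if (abs(ar1_coef) >= 1) stop("|ar1_coef| must be < 1", call. = FALSE)
  if (daily_sd < 0) stop("daily_sd must be >= 0", call. = FALSE)
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (is.na(start_date) || is.na(end_date) || end_date < start_date) {
    stop("invalid date range in climate_params", call. = FALSE)
  }
  structure(list(mean_temp = mean_temp,
                 seasonal_amplitude = seasonal_amplitude,
                 phase = phase, ar1_coef = ar1_coef, daily_sd = daily_sd,
                 start_date = start_date, end_date = end_date),
            class = "climate_params")
}

#' Seasonal component of the annual temperature cycle.
#' @noRd
seasonal_cycle <- function(params, dates) {
  doy <- as.POSIXlt(dates)$yday + 1L
  params$seasonal_amplitude * cos(2 * pi * doy / 365.25 - params$phase)
}

#' AR(1) residual stream with marginal SD `daily_sd`.
#' @noRd
ar1_residuals <- function(params, n, seed) {
  if (params$daily_sd == 0 || n == 0L) return(numeric(n))
  with_seed(seed, {
    innov_sd <- params$daily_sd * sqrt(1 - params$ar1_coef^2)
    e0 <- rnorm(1, 0, params$daily_sd)
    innov <- rnorm(n, 0, innov_sd)
    as.numeric(stats::filter(innov, params$ar1_coef,
                             method = "recursive", init = e0))
  })
}

#' Generate a synthetic daily temperature series
#'
#' One value per calendar day (proleptic Gregorian, leap days included):
#' `mean_temp + seasonal cycle + AR(1) residual`.  Identical parameters
#' and seed give a bit-identical series.
#'
#' @param params a [climate_params()] object.
#' @param seed integer seed for the residual stream.
#' @return a data frame with columns `date`, `tmean`, carrying the
#'   generating parameters in attribute `climate_params`.
#' @export
make_climate <- function(params, seed = 1L) {
  stopifnot(inherits(params, "climate_params"))
  dates <- date_seq(params$start_date, params$end_date)
  tmean <- params$mean_temp + seasonal_cycle(params, dates) +
    ar1_residuals(params, length(dates), seed)
  structure(data.frame(date = dates, tmean = tmean),
            climate_params = params)
}
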