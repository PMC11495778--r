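#' Configuration of a pseudo-ESM scenario temperature series
#'
#' Describes one (model, scenario) cell of the projection design: a
#' number of ensemble members, an additive bias relative to the observed
#' climate, a linear warming trend, and a residual-variability scale.
#' The conventional scenario names follow the land-use experiment design:
#' a `noLULCC` control plus `sustainability` and `inequality` land-use
#' scenarios; ESMs are run as three-member ensembles.
#'
#' @param scenario_name one of `"noLULCC"`, `"sustainability"`,
#'   `"inequality"`.
#' @param model_name label of the pseudo earth-system model.
#' @param n_members number of ensemble members, >= 1 (default 3).
#' @param additive_bias constant model bias (degrees C).
#' @param trend_per_decade linear trend (degrees C per decade from the
#'   horizon start).
#' @param variability_scale multiplier on the day-to-day residual SD, > 0.
#' @param horizon_start,horizon_end first/last simulated year.
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(scenario_name = c("noLULCC", "sustainability",
                                              "inequality"),
                            model_name = "ESM1",
                            n_members = 3L,
                            additive_bias = 0,
                            trend_per_decade = 0,
                            variability_scale = 1,
                            horizon_start = 1980L,
                            horizon_end = 2099L) {
  scenario_name <- match.arg(scenario_name)
  if (n_members < 1L) stop("n_members must be >= 1", call. = FALSE)
  if (variability_scale <= 0) stop("variability_scale must be > 0", call. = FALSE)
  if (horizon_end < horizon_start) stop("empty scenario horizon", call. = FALSE)
  structure(list(scenario_name = scenario_name, model_name = model_name,
                 n_members = as.integer(n_members),
                 additive_bias = additive_bias,
                 trend_per_decade = trend_per_decade,
                 variability_scale = variability_scale,
                 horizon_start = as.integer(horizon_start),
                 horizon_end = as.integer(horizon_end)),
            class = "scenario_config")
}

#' Generate pseudo-ESM daily temperature series for one scenario
#'
#' Each ensemble member shares the observed location's seasonal cycle and
#' AR(1) residual law (taken from the generator parameters attached to
#' the observed series) and adds the configured bias, linear trend and
#' residual rescaling.  Members differ only through their RNG substream.
#' The horizon must cover the observed record, otherwise the later bias
#' calibration would have no overlap to work with.
#'
#' @param obs_temps an observed series carrying a `climate_params`
#'   attribute ([make_climate()] or [simulate_mortality()] output).
#' @param cfg a [scenario_config()].
#' @param seed master seed; member streams are derived from it.
#' @return a data frame `model,scenario,member,date,tmean` with the
#'   config in attribute `scenario_config`.
#' @export
make_scenario_series <- function(obs_temps, cfg, seed = 1L) {
  stopifnot(inherits(cfg, "scenario_config"))
  params <- attr(obs_temps, "climate_params")
  if (is.null(params)) {
    stop("obs_temps must carry a climate_params attribute", call. = FALSE)
  }
  obs_years <- as.integer(format(as.Date(range(obs_temps$date)), "%Y"))
  if (obs_years[1] < cfg$horizon_start || obs_years[2] > cfg$horizon_end) {
    stop("scenario horizon does not cover the observed window; calibration would be impossible",
         call. = FALSE)
  }
  dates <- date_seq(sprintf("%d-01-01", cfg$horizon_start),
                    sprintf("%d-12-31", cfg$horizon_end))
  years_since <- as.numeric(dates - as.Date(sprintf("%d-01-01", cfg$horizon_start))) / 365.25
  seasonal <- params$mean_temp + seasonal_cycle(params, dates)
  drift <- cfg$additive_bias + cfg$trend_per_decade * years_since / 10
  out <- vector("list", cfg$n_members)
  for (m in seq_len(cfg$n_members)) {
    member_seed <- substream_seed(seed, c(cfg$model_name, cfg$scenario_name, m))
    resid <- ar1_residuals(params, length(dates), member_seed)
    out[[m]] <- data.frame(model = cfg$model_name,
                           scenario = cfg$scenario_name,
                           member = m, date = dates,
                           tmean = seasonal + drift + cfg$variability_scale * resid)
  }
  structure(do.call(rbind, out), scenario_config = cfg)
}
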