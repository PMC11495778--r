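#' Trend-preserving bias calibration of a scenario temperature series
#'
#' Additive monthly-offset adjustment with residual variance scaling: for
#' each calendar month m, the offset `C_m = mean(obs, m) - mean(model, m)`
#' over the calibration window is added to every day of month m across
#' the whole series, and the daily residuals about each (year, month)
#' mean are multiplied by `s_m = sd(obs resid, m) / sd(model resid, m)`
#' computed on the window.  Because the offset is constant within a
#' calendar month and residuals average to zero within each month cell,
#' the window monthly means of the adjusted series equal the observed
#' monthly means exactly, while the model's long-term (month-wise) change
#' signal is untouched.
#'
#' @param model_series data frame `date`, `tmean` (one member of one
#'   model/scenario; extra id columns are preserved).
#' @param obs_series data frame `date`, `tmean` of observations.
#' @param window calendar-year range `c(first, last)` of the calibration
#'   window; it is intersected with the overlap of both series (default
#'   1980-2014).
#' @return the model series with calibrated `tmean`, plus attributes
#'   `offsets` (12 monthly offsets, degrees C), `scales` (12 residual
#'   scale factors) and `window` (the years actually used).
#' @export
calibrate_bias <- function(model_series, obs_series, window = c(1980, 2014)) {
  md <- as.Date(model_series$date)
  od <- as.Date(obs_series$date)
  my <- as.integer(format(md, "%Y"))
  oy <- as.integer(format(od, "%Y"))
  yrs <- intersect(intersect(unique(my), unique(oy)),
                   seq(window[1], window[2]))
  if (!length(yrs)) {
    stop("model and observed series have no overlap on the calibration window",
         call. = FALSE)
  }
  mm <- as.integer(format(md, "%m"))
  om <- as.integer(format(od, "%m"))

  # (year, month) cell means and residuals for the full model series
  mcell <- paste(my, mm)
  cell_mean <- tapply(model_series$tmean, mcell, mean)
  mfit <- as.numeric(cell_mean[mcell])
  mres <- model_series$tmean - mfit

  ocell <- paste(oy, om)
  ocell_mean <- tapply(obs_series$tmean, ocell, mean)
  ores <- obs_series$tmean - as.numeric(ocell_mean[ocell])

  in_mwin <- my %in% yrs
  in_owin <- oy %in% yrs
  offsets <- numeric(12)
  scales <- rep(1, 12)
  for (m in 1:12) {
    mw <- in_mwin & mm == m
    ow <- in_owin & om == m
    offsets[m] <- mean(obs_series$tmean[ow]) - mean(model_series$tmean[mw])
    sd_model <- sd(mres[mw])
    sd_obs <- sd(ores[ow])
    if (is.na(sd_model) || sd_model == 0) {
      warning(sprintf("zero model residual SD in month %d; scale factor set to 1", m))
    } else {
      scales[m] <- sd_obs / sd_model
    }
  }
  out <- model_series
  out$tmean <- mfit + offsets[mm] + scales[mm] * mres
  structure(out, offsets = offsets, scales = scales, window = range(yrs))
}

#' Constant day-of-year baseline mortality series
#'
#' Averages the observed death counts for each day of the year and
#' repeats the profile along the projection period, encoding the
#' assumption that baseline mortality (demography, population size) is
#' constant over time.  Feb 29 uses the mean over observed Feb 29s when
#' any exist, otherwise the mean of the Feb 28 and Mar 1 profiles.
#'
#' @param obs_series data frame `date`, `deaths` of the observed record.
#' @param start_year,end_year projection period (default 1980-2099).
#' @return an object of class `baseline_mortality`: `profile` (366
#'   day-of-year means keyed "mm-dd") and `series` (data frame `date`,
#'   `deaths` over the projection period).
#' @export
baseline_mortality <- function(obs_series, start_year = 1980L,
                               end_year = 2099L) {
  if (!nrow(obs_series)) stop("empty observed series", call. = FALSE)
  key <- monthday(obs_series$date)
  prof <- tapply(obs_series$deaths, key, mean)
  if (!"02-29" %in% names(prof)) {
    prof <- c(prof, `02-29` = unname((prof["02-28"] + prof["03-01"]) / 2))
  }
  if (any(prof < 0)) stop("negative baseline mortality", call. = FALSE)
  dates <- date_seq(sprintf("%d-01-01", start_year),
                    sprintf("%d-12-31", end_year))
  series <- data.frame(date = dates,
                       deaths = as.numeric(prof[monthday(dates)]))
  structure(list(profile = prof, series = series),
            class = "baseline_mortality")
}

#' Project daily excess mortality under one calibrated scenario series
#'
#' Applies the attribution machinery to the calibrated scenario
#' temperatures and the constant baseline mortality: daily attributable
#' deaths relative to the (fixed, historically estimated) MMT, tagged
#' cold or heat by the side of the MMT the day falls on.
#'
#' @param calibrated calibrated scenario series (`date`, `tmean`, id
#'   columns preserved).
#' @param baseline a [baseline_mortality()] object (or its `series`).
#' @param curve the location's BLUP (or reduced) curve.
#' @param mmt the location's MMT (object or degrees C).
#' @return data frame `date`, `tmean`, `deaths`, `an`, `an_cold`,
#'   `an_heat` (daily values; `an = an_cold + an_heat`).
#' @export
project_em <- function(calibrated, baseline, curve, mmt) {
  bs <- if (inherits(baseline, "baseline_mortality")) baseline$series else baseline
  idx <- match(as.Date(calibrated$date), as.Date(bs$date))
  if (anyNA(idx)) {
    stop("baseline mortality does not cover the scenario dates", call. = FALSE)
  }
  deaths <- bs$deaths[idx]
  an <- attributable_numbers(calibrated$tmean, deaths, curve, mmt)
  m <- if (inherits(mmt, "mmt")) mmt$value else as.numeric(mmt)
  data.frame(date = calibrated$date, tmean = calibrated$tmean,
             deaths = deaths,
             an = as.numeric(an),
             an_cold = as.numeric(an) * (calibrated$tmean < m),
             an_heat = as.numeric(an) * (calibrated$tmean > m))
}

#' Decadal sums of attributable deaths and baseline deaths
#'
#' Collapses a daily projection table to one row per (location, model,
#' scenario, member, decade).  Useful to keep long multi-run projections
#' compact before [aggregate_projection()].
#'
#' @param daily data frame with `location`, `model`, `scenario`,
#'   `member`, `date`, `deaths`, `an_cold`, `an_heat`.
#' @return data frame of decade sums with an `an_total` column.
#' @export
decade_sums <- function(daily) {
  daily$decade <- decade_of(daily$date)
  sums <- aggregate(
    cbind(an_cold, an_heat, deaths) ~ location + model + scenario + member + decade,
    data = daily, FUN = sum)
  sums$an_total <- sums$an_cold + sums$an_heat
  sums
}

#' Decadal aggregation, scenario differencing and multimodel averaging
#'
#' Consumes a tidy daily projection table (one row per location, model,
#' scenario, member, day), or the pre-collapsed output of
#' [decade_sums()], and produces, in order:
#' \enumerate{
#'   \item decadal excess-mortality fractions per (location, model,
#'     scenario, member, decade, component): `100 * sum(AN) /
#'     sum(baseline deaths)` within the decade;
#'   \item deltas in percentage points: for the control scenario
#'     (`reference_scenario`), each decade minus the same run's
#'     `reference_decade` (1980-1989); for every other scenario, the
#'     scenario decade minus the control's same decade, same model and
#'     member;
#'   \item ensemble means over members, then multimodel means over
#'     models (fixed aggregation order);
#'   \item regional aggregates: death-weighted pooled fractions
#'     (`100 * sum_loc AN / sum_loc deaths`), with the same differencing.
#' }
#'
#' @param daily data frame with columns `location`, `model`, `scenario`,
#'   `member`, `date`, `deaths`, `an_cold`, `an_heat`.
#' @param region_map data frame `location`, `region`.
#' @param decades character vector of decade labels to report (default
#'   all complete decades present).
#' @param reference_scenario control scenario name (default `"noLULCC"`).
#' @param reference_decade historical reference decade label.
#' @return an object of class `projection_result`: data frames
#'   `by_member`, `by_model` (ensemble means), `multimodel`
#'   (multimodel means, per location), `regional` (death-weighted,
#'   multimodel means per region).  All fraction columns are percentages;
#'   delta columns are percentage points.
#' @export
aggregate_projection <- function(daily, region_map,
                                 decades = NULL,
                                 reference_scenario = "noLULCC",
                                 reference_decade = "1980-1989") {
  need <- c("location", "model", "scenario", "member", "deaths",
            "an_cold", "an_heat")
  stopifnot(all(need %in% names(daily)))
  sums <- if ("date" %in% names(daily)) decade_sums(daily) else daily
  if (is.null(sums$an_total)) sums$an_total <- sums$an_cold + sums$an_heat
  if (is.null(decades)) decades <- sort(unique(sums$decade))
  decades <- union(reference_decade, decades)
  sums <- sums[sums$decade %in% decades, , drop = FALSE]

  # long format over components, decadal fractions
  long <- function(df, id_cols) {
    comp <- do.call(rbind, lapply(c("cold", "heat", "total"), function(cmp) {
      out <- df[id_cols]
      out$component <- cmp
      out$an <- df[[paste0("an_", cmp)]]
      out$deaths <- df$deaths
      out
    }))
    comp$fraction_pct <- 100 * comp$an / comp$deaths
    comp
  }
  by_member <- long(sums, c("location", "model", "scenario", "member", "decade"))

  add_deltas <- function(df, keys) {
    # reference 1: control scenario's historical decade, same run
    ctrl <- df[df$scenario == reference_scenario, , drop = FALSE]
    if (!nrow(ctrl)) {
      stop(sprintf("missing reference scenario '%s'", reference_scenario),
           call. = FALSE)
    }
    hist_ref <- ctrl[ctrl$decade == reference_decade, , drop = FALSE]
    if (!nrow(hist_ref)) {
      stop(sprintf("missing reference decade '%s' in scenario '%s'",
                   reference_decade, reference_scenario), call. = FALSE)
    }
    kh <- c(keys, "component")
    key_of <- function(d, cols) do.call(paste, c(d[cols], sep = "\r"))
    hist_val <- setNames(hist_ref$fraction_pct, key_of(hist_ref, kh))
    ctrl_val <- setNames(ctrl$fraction_pct, key_of(ctrl, c(kh, "decade")))
    is_ctrl <- df$scenario == reference_scenario
    ref <- numeric(nrow(df))
    ref[is_ctrl] <- hist_val[key_of(df[is_ctrl, , drop = FALSE], kh)]
    ref[!is_ctrl] <- ctrl_val[key_of(df[!is_ctrl, , drop = FALSE], c(kh, "decade"))]
    if (anyNA(ref)) {
      gaps <- unique(df[is.na(ref), c(keys, "scenario", "decade"), drop = FALSE])
      stop(paste0("incomplete projection design; missing control cells for: ",
                  paste(utils::capture.output(print(utils::head(gaps, 5L))),
                        collapse = "\n")), call. = FALSE)
    }
    df$delta_pp <- df$fraction_pct - ref
    df
  }
  by_member <- add_deltas(by_member, c("location", "model", "member"))

  by_model <- aggregate(cbind(fraction_pct, delta_pp) ~
                          location + model + scenario + decade + component,
                        data = by_member, FUN = mean)
  multimodel <- aggregate(cbind(fraction_pct, delta_pp) ~
                            location + scenario + decade + component,
                          data = by_model, FUN = mean)

  # regional: death-weighted pooling of AN before the fraction
  rm_idx <- match(sums$location, region_map$location)
  if (anyNA(rm_idx)) {
    stop(sprintf("locations missing from the region map: %s",
                 paste(unique(sums$location[is.na(rm_idx)]), collapse = ", ")),
         call. = FALSE)
  }
  sums$region <- region_map$region[rm_idx]
  rsums <- aggregate(cbind(an_cold, an_heat, an_total, deaths) ~
                       region + model + scenario + member + decade,
                     data = sums, FUN = sum)
  regional_member <- long(rsums, c("region", "model", "scenario", "member", "decade"))
  regional_member <- add_deltas(regional_member, c("region", "model", "member"))
  regional_model <- aggregate(cbind(fraction_pct, delta_pp) ~
                                region + model + scenario + decade + component,
                              data = regional_member, FUN = mean)
  regional <- aggregate(cbind(fraction_pct, delta_pp) ~
                          region + scenario + decade + component,
                        data = regional_model, FUN = mean)

  sort_df <- function(d) d[do.call(order, d[setdiff(names(d),
                                                    c("an", "deaths", "fraction_pct", "delta_pp"))]), ,
                           drop = FALSE]
  structure(list(by_member = sort_df(by_member),
                 by_model = sort_df(by_model),
                 multimodel = sort_df(multimodel),
                 regional = sort_df(regional),
                 reference_scenario = reference_scenario,
                 reference_decade = reference_decade),
            class = "projection_result")
}

#' Monte-Carlo confidence intervals for decadal projected fractions
#'
#' Exactly the attribution-stage resampling scheme applied to a
#' projection run: coefficient draws from the curve's covariance, MMT
#' held fixed, decadal excess-mortality fractions recomputed per draw,
#' empirical percentile intervals reported per decade and component.
#'
#' @param calibrated calibrated scenario series (`date`, `tmean`).
#' @param baseline a [baseline_mortality()] object (or its `series`).
#' @param curve the location's BLUP (or reduced) curve.
#' @param mmt the location's MMT (object or degrees C).
#' @param decades decade labels to report (e.g. `"2090-2099"`).
#' @param n_samples coefficient draws (default 1000).
#' @param seed integer seed.
#' @param level confidence level.
#' @param chunk draws processed per block (memory control).
#' @return data frame `decade`, `component`, `ci_low`, `ci_high`
#'   (fraction percentages).
#' @export
project_decade_ci <- function(calibrated, baseline, curve, mmt, decades,
                              n_samples = 1000L, seed = 1L, level = 0.95,
                              chunk = 250L) {
  bs <- if (inherits(baseline, "baseline_mortality")) baseline$series else baseline
  curve <- center_at_mmt(curve, mmt)
  m <- curve$center
  dec <- decade_of(calibrated$date)
  keep <- dec %in% decades
  temps <- calibrated$tmean[keep]
  idx <- match(as.Date(calibrated$date[keep]), as.Date(bs$date))
  if (anyNA(idx)) stop("baseline does not cover the scenario dates", call. = FALSE)
  deaths <- bs$deaths[idx]
  dec <- dec[keep]
  D <- curve_basis(curve, temps)
  draws <- with_seed(seed,
                     rmvnorm_psd(n_samples, curve$coef, curve$vcov,
                                 label = "coefficient covariance"))
  dec_f <- factor(dec, levels = sort(unique(dec)))
  cold_rows <- temps < m
  heat_rows <- temps > m
  denom <- tapply(deaths, dec_f, sum)
  res <- list()
  for (start in seq(1L, n_samples, by = chunk)) {
    cols <- start:min(start + chunk - 1L, n_samples)
    eta <- D %*% t(draws[cols, , drop = FALSE])
    anm <- (1 - exp(-eta)) * deaths
    res[[length(res) + 1L]] <- lapply(list(cold = cold_rows, heat = heat_rows,
                                           total = rep(TRUE, length(temps))),
      function(mask) {
        rowsum(anm * mask, dec_f)  # decades x draws
      })
  }
  pr <- c((1 - level) / 2, 1 - (1 - level) / 2)
  out <- do.call(rbind, lapply(c("cold", "heat", "total"), function(cmp) {
    an_mat <- do.call(cbind, lapply(res, `[[`, cmp))
    frac <- 100 * an_mat / as.numeric(denom)
    data.frame(decade = rownames(an_mat), component = cmp,
               ci_low = apply(frac, 1, quantile, pr[1], type = 7),
               ci_high = apply(frac, 1, quantile, pr[2], type = 7))
  }))
  rownames(out) <- NULL
  out[order(out$decade, out$component), ]
}
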