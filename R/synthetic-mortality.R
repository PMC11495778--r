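#' Normalised lag weights for the true exposure-lag-response surface
#'
#' The ground-truth surface factorises as `w(l) * f(x)`: a single overall
#' cumulative curve distributed over the lag window by non-negative
#' weights summing to one.  The geometric profile concentrates effect at
#' short lags; `cold_long` shifts mass towards long lags the way cold
#' effects accumulate over weeks, `heat_short` the opposite.
#'
#' @param max_lag maximum lag L (days).
#' @param profile one of `"geometric"`, `"heat_short"`, `"cold_long"`.
#' @param rate decay rate of the geometric profile, in (0, 1).
#' @return numeric vector of length `L + 1` summing to 1.
#' @export
lag_weights <- function(max_lag = 21L,
                        profile = c("geometric", "heat_short", "cold_long"),
                        rate = 0.75) {
  profile <- match.arg(profile)
  l <- 0:max_lag
  w <- switch(profile,
    geometric = rate^l,
    heat_short = 0.4^l,
    cold_long = (l + 1) * 0.85^l
  )
  w / sum(w)
}

#' Ground-truth temperature-mortality association
#'
#' A U-shaped (convex) overall cumulative log-relative-risk curve,
#' piecewise quadratic around a true minimum mortality temperature:
#' `f(x) = cold_slope * (mmt - x)^2` below the MMT and
#' `heat_slope * (x - mmt)^2` above it, together with a lag-weight
#' vector distributing the log-risk over the lag window.
#'
#' @param true_mmt true minimum mortality temperature (degrees C).
#' @param cold_slope,heat_slope curvature per squared degree, >= 0.
#' @param weights lag weights from [lag_weights()].
#' @return an object of class `true_association`.
#' @export
true_association <- function(true_mmt = 19,
                             cold_slope = 8e-4,
                             heat_slope = 3e-3,
                             weights = lag_weights()) {
  if (cold_slope < 0 || heat_slope < 0) {
    stop("curve slopes must be non-negative (convex U-shape)", call. = FALSE)
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-10) {
    stop("lag weights must be non-negative and sum to 1", call. = FALSE)
  }
  structure(list(true_mmt = true_mmt, cold_slope = cold_slope,
                 heat_slope = heat_slope, weights = as.numeric(weights)),
            class = "true_association")
}

#' Evaluate the true overall cumulative log-RR curve.
#'
#' @param assoc a [true_association()].
#' @param x temperatures (degrees C).
#' @return log relative risk, zero at the true MMT.
#' @export
eval_association <- function(assoc, x) {
  d <- x - assoc$true_mmt
  assoc$cold_slope * pmin(d, 0)^2 + assoc$heat_slope * pmax(d, 0)^2
}

#' Baseline (temperature-independent) mortality parameters
#'
#' Log-scale intercept, an annual harmonic (mortality peaks in winter for
#' `phase = 0` in the northern-hemisphere convention used here), weekday
#' offsets, and a quasi-Poisson-style variance inflation factor.
#'
#' @param intercept log expected deaths/day at the seasonal midpoint.
#' @param seasonal_amplitude amplitude of the log-scale annual cycle.
#' @param phase phase of the baseline annual harmonic (radians).
#' @param dow_effects 7 log-scale offsets (Sunday first, per `POSIXlt$wday`).
#' @param overdispersion variance/mean ratio of daily counts, >= 1.
#' @return an object of class `baseline_params`.
#' @export
baseline_params <- function(intercept = log(30),
                            seasonal_amplitude = 0.12,
                            phase = 0,
                            dow_effects = c(0, 0, 0, 0, 0, 0.01, 0.01),
                            overdispersion = 1.3) {
  if (overdispersion < 1) stop("overdispersion must be >= 1", call. = FALSE)
  if (length(dow_effects) != 7L) stop("dow_effects must have length 7", call. = FALSE)
  structure(list(intercept = intercept,
                 seasonal_amplitude = seasonal_amplitude, phase = phase,
                 dow_effects = as.numeric(dow_effects),
                 overdispersion = overdispersion),
            class = "baseline_params")
}

#' Log-scale baseline mortality for a vector of dates.
#' @noRd
baseline_log_mu <- function(base, dates) {
  lt <- as.POSIXlt(dates)
  doy <- lt$yday + 1L
  base$intercept +
    base$seasonal_amplitude * cos(2 * pi * doy / 365.25 - base$phase) +
    base$dow_effects[lt$wday + 1L]
}

#' Simulate daily death counts from a known exposure-lag-response surface
#'
#' Counts are drawn with mean `mu_t = exp(baseline_t + sum_l w(l) *
#' f(T[t-l]))` and variance `overdispersion * mu_t`, using a gamma-Poisson
#' (negative binomial) mixture matched on the first two moments: the
#' quasi-Poisson likelihood used in fitting has no generative form, and
#' the gamma mixture is its standard simulation surrogate.  The first L
#' days have no complete lag window; their counts are drawn from the
#' baseline alone and flagged as burn-in, to be excluded from fitting.
#'
#' @param temps a `date`/`tmean` data frame from [make_climate()].
#' @param assoc a [true_association()].
#' @param base a [baseline_params()].
#' @param seed integer seed for the count draws.
#' @param location optional location id stored on the result.
#' @return a `location_series`: data frame `date`, `tmean`, `deaths` with
#'   attributes `mu` (the generator's mean), `burnin` (logical flags),
#'   `assoc`, `base`, `location` and the inherited `climate_params`.
#' @export
simulate_mortality <- function(temps, assoc, base, seed = 1L,
                               location = "loc1") {
  stopifnot(inherits(assoc, "true_association"),
            inherits(base, "baseline_params"))
  L <- length(assoc$weights) - 1L
  n <- nrow(temps)
  if (n < L + 1L) {
    stop("temperature series shorter than the lag window", call. = FALSE)
  }
  fx <- eval_association(assoc, temps$tmean)
  eta <- as.numeric(stats::filter(fx, assoc$weights,
                                  method = "convolution", sides = 1))
  burnin <- is.na(eta)
  eta[burnin] <- 0
  mu <- exp(baseline_log_mu(base, temps$date) + eta)
  deaths <- with_seed(seed, {
    d <- base$overdispersion
    if (d == 1) {
      rpois(n, mu)
    } else {
      rnbinom(n, mu = mu, size = mu / (d - 1))
    }
  })
  storage.mode(deaths) <- "integer"
  structure(data.frame(date = temps$date, tmean = temps$tmean,
                       deaths = deaths),
            mu = mu, burnin = burnin, assoc = assoc, base = base,
            location = location,
            climate_params = attr(temps, "climate_params"),
            class = c("location_series", "data.frame"))
}
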