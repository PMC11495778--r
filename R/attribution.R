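#' Locate the minimum mortality temperature
#'
#' Searches the predicted overall cumulative log relative risk over a
#' grid of the location's empirical temperature percentiles (integer
#' percentiles, linear-interpolation quantiles) restricted to a window
#' that keeps the search away from the unstable spline tails (default
#' 1st-99th percentile).  Ties are broken towards the lowest tied
#' temperature; a minimum on the window edge is flagged, since it usually
#' signals a curve monotone over the window.
#'
#' @param curve a `reduced_curve` or BLUP.
#' @param temps the location's observed daily temperatures.
#' @param window percentile window `c(low, high)` searched, in (0, 100).
#' @return an object of class `mmt`: `value` (degrees C), `percentile`,
#'   `boundary` flag, and the grid searched.
#' @export
find_mmt <- function(curve, temps, window = c(1, 99)) {
  stopifnot(inherits(curve, "reduced_curve"), length(window) == 2L)
  pct <- seq(ceiling(window[1]), floor(window[2]))
  grid <- as.numeric(quantile(temps, pct / 100, type = 7, na.rm = TRUE))
  logrr <- drop(curve_basis(curve, grid) %*% curve$coef)
  idx <- which.min(logrr)  # first index = lowest tied temperature
  boundary <- idx == 1L || idx == length(grid)
  if (boundary) {
    warning("minimum mortality temperature lies on the search-window boundary")
  }
  structure(list(value = grid[idx], percentile = pct[idx],
                 boundary = boundary, grid = grid, window = window),
            class = "mmt")
}

#' Re-center a curve at the minimum mortality temperature.
#'
#' @param curve a `reduced_curve`.
#' @param mmt an [find_mmt()] result or a temperature in degrees C.
#' @return the curve with its centering value replaced.
#' @export
center_at_mmt <- function(curve, mmt) {
  curve$center <- if (inherits(mmt, "mmt")) mmt$value else as.numeric(mmt)
  curve
}

#' Daily attributable deaths (backward attributable fraction)
#'
#' For each day, `AF_t = 1 - exp(-eta_t)` with `eta_t` the overall
#' cumulative log relative risk of that day's temperature relative to the
#' minimum mortality temperature, and `AN_t = AF_t * deaths_t`.
#'
#' @param temps daily temperatures.
#' @param deaths daily death counts (observed or baseline).
#' @param curve a `reduced_curve`/BLUP.
#' @param mmt an `mmt` object or temperature; the curve is re-centered
#'   there.
#' @return numeric vector of daily attributable numbers, with the daily
#'   attributable fractions in attribute `af` and the share of days
#'   beyond the basis boundary in attribute `extrapolation_share`.
#' @export
attributable_numbers <- function(temps, deaths, curve, mmt) {
  if (length(temps) != length(deaths)) {
    stop("temps and deaths have different lengths", call. = FALSE)
  }
  curve <- center_at_mmt(curve, mmt)
  eta <- drop(curve_basis(curve, temps) %*% curve$coef)
  af <- 1 - exp(-eta)
  an <- af * deaths
  extra <- mean(temps < curve$var_boundary[1] | temps > curve$var_boundary[2])
  structure(an, af = af, extrapolation_share = extra)
}

#' Split total attributable deaths into cold and heat components
#'
#' Cold sums the days strictly below the MMT, heat the days strictly
#' above; days exactly at the MMT contribute to neither (their
#' attributable fraction is zero by construction).
#'
#' @param an daily attributable numbers.
#' @param temps the matching daily temperatures.
#' @param mmt an `mmt` object or temperature.
#' @return named vector `c(cold =, heat =, total =)` with
#'   `cold + heat == total` exactly.
#' @export
split_cold_heat <- function(an, temps, mmt) {
  if (length(an) != length(temps)) {
    stop("an and temps have different lengths", call. = FALSE)
  }
  m <- if (inherits(mmt, "mmt")) mmt$value else as.numeric(mmt)
  cold <- sum(an[temps < m])
  heat <- sum(an[temps > m])
  c(cold = cold, heat = heat, total = cold + heat)
}

#' Excess-mortality fraction
#'
#' Attributable deaths as a percentage of all deaths in the period.
#'
#' @param an attributable-death totals (scalar or vector, e.g. the
#'   cold/heat/total triple).
#' @param total_deaths denominator: total deaths over the same period.
#' @return percentages.
#' @export
excess_fraction <- function(an, total_deaths) {
  if (total_deaths <= 0) stop("total deaths must be positive", call. = FALSE)
  100 * an / total_deaths
}

#' Monte-Carlo empirical confidence intervals for attributable deaths
#'
#' Draws `n_samples` coefficient vectors from a multivariate normal
#' centered at the curve's coefficients with its covariance, recomputes
#' the cold/heat/total attributable totals for each draw with the MMT
#' held fixed at its central estimate, and reports empirical percentile
#' intervals (2.5th/97.5th by default, following the 1000-sample
#' convention of the attribution literature).
#'
#' @param curve a `reduced_curve`/BLUP with covariance.
#' @param temps,deaths daily series.
#' @param mmt the central-estimate MMT.
#' @param n_samples number of coefficient draws (default 1000).
#' @param seed integer seed.
#' @param level confidence level.
#' @return an object of class `attribution_ci`: point estimates, CI
#'   bounds per component, the fractions, and the draw matrix summary.
#' @export
monte_carlo_ci <- function(curve, temps, deaths, mmt, n_samples = 1000L,
                           seed = 1L, level = 0.95) {
  stopifnot(inherits(curve, "reduced_curve"))
  curve <- center_at_mmt(curve, mmt)
  m <- curve$center
  D <- curve_basis(curve, temps)
  draws <- with_seed(seed,
                     rmvnorm_psd(n_samples, curve$coef, curve$vcov,
                                 label = "coefficient covariance"))
  eta <- D %*% t(draws)                       # n_days x n_samples
  anm <- (1 - exp(-eta)) * deaths
  cold_s <- colSums(anm[temps < m, , drop = FALSE])
  heat_s <- colSums(anm[temps > m, , drop = FALSE])
  total_s <- cold_s + heat_s
  point <- split_cold_heat(attributable_numbers(temps, deaths, curve, m),
                           temps, m)
  pr <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ci <- rbind(cold = quantile(cold_s, pr, type = 7),
              heat = quantile(heat_s, pr, type = 7),
              total = quantile(total_s, pr, type = 7))
  colnames(ci) <- c("low", "high")
  structure(list(point = point, ci = ci,
                 fraction = excess_fraction(point, sum(deaths)),
                 fraction_ci = excess_fraction(ci, sum(deaths)),
                 n_samples = n_samples, level = level,
                 samples = cbind(cold = cold_s, heat = heat_s,
                                 total = total_s)),
            class = "attribution_ci")
}

#' Full attribution summary for one location
#'
#' Convenience wrapper: finds the MMT, computes daily attributable
#' numbers, splits them, and attaches fractions and Monte-Carlo CIs.
#'
#' @param series a `location_series`.
#' @param curve the location's curve (first-stage or BLUP).
#' @param window MMT percentile search window.
#' @param n_samples,seed Monte-Carlo settings.
#' @return a tidy data frame: one row per component with `an`,
#'   `fraction_pct`, `ci_low`, `ci_high` (fraction scale), plus the MMT
#'   in attribute `mmt`.
#' @export
attribute_location <- function(series, curve, window = c(1, 99),
                               n_samples = 1000L, seed = 1L) {
  mmt <- find_mmt(curve, series$tmean, window)
  mc <- monte_carlo_ci(curve, series$tmean, series$deaths, mmt,
                       n_samples = n_samples, seed = seed)
  out <- data.frame(location = curve$location,
                    component = c("cold", "heat", "total"),
                    an = as.numeric(mc$point),
                    fraction_pct = as.numeric(mc$fraction),
                    ci_low = as.numeric(mc$fraction_ci[, "low"]),
                    ci_high = as.numeric(mc$fraction_ci[, "high"]))
  structure(out, mmt = mmt)
}
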