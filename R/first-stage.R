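#' Control parameters of the first-stage time-series regression
#'
#' @param seasonal_df_per_year degrees of freedom per year of the natural
#'   cubic spline of elapsed time that absorbs seasonality and long-term
#'   trend (default 8, the multi-city convention).
#' @param epsilon IRLS convergence tolerance on the relative deviance
#'   change.
#' @param maxit maximum IRLS iterations.
#' @return a list of class `fit_control`.
#' @export
fit_control <- function(seasonal_df_per_year = 8, epsilon = 1e-9,
                        maxit = 100L) {
  structure(list(seasonal_df_per_year = seasonal_df_per_year,
                 epsilon = epsilon, maxit = as.integer(maxit)),
            class = "fit_control")
}

#' Confounder block: time spline + day-of-week indicators.
#' @noRd
confounder_matrix <- function(dates, control) {
  n <- length(dates)
  nyears <- n / 365.25
  df_seas <- max(2L, round(control$seasonal_df_per_year * nyears))
  tm <- splines::ns(seq_len(n), df = df_seas)
  tm <- matrix(as.numeric(tm), nrow = n)
  colnames(tm) <- paste0("time", seq_len(ncol(tm)))
  wday <- as.POSIXlt(dates)$wday
  dow <- matrix(0, n, 6L)
  for (d in 1:6) dow[, d] <- as.numeric(wday == d)
  colnames(dow) <- paste0("dow", 1:6)
  cbind(tm, dow)
}

#' Fit the location-specific distributed lag nonlinear model
#'
#' Quasi-Poisson time-series regression of daily deaths on the
#' temperature cross-basis, with a natural cubic spline of time (default
#' 8 df/year) and day-of-week indicators as confounders.  The model is a
#' log-link Poisson-family GLM fitted by iteratively reweighted least
#' squares; the quasi-Poisson dispersion `phi` is the Pearson chi-square
#' divided by the residual degrees of freedom, and the covariance of the
#' cross-basis coefficient block is `phi * (X'WX)^-1` restricted to that
#' block.  Days with a missing temperature anywhere in their lag window,
#' missing deaths, or within the initial burn-in are dropped from the
#' likelihood (lags are computed on the original calendar, so gaps
#' propagate incompleteness).
#'
#' @param series a `location_series` (or any data frame with `date`,
#'   `tmean`, `deaths`).
#' @param spec a [cross_basis_spec()]; resolved against this location's
#'   temperatures if not already resolved.
#' @param control a [fit_control()].
#' @return an object of class `first_stage_fit`: coefficients, the
#'   cross-basis coefficient block `gamma` with covariance `vcov_gamma`,
#'   dispersion `phi`, the resolved `spec`, convergence info, and the
#'   design matrix / response retained for diagnostics.
#' @export
fit_location <- function(series, spec = cross_basis_spec(),
                         control = fit_control()) {
  stopifnot(all(c("date", "tmean", "deaths") %in% names(series)))
  if (any(series$deaths < 0, na.rm = TRUE)) {
    stop("negative death counts", call. = FALSE)
  }
  n <- nrow(series)
  if (n < 2 * 365) stop("need at least 2 years of data", call. = FALSE)
  cb <- build_cross_basis(series$tmean, spec)
  spec <- attr(cb, "spec")
  conf <- confounder_matrix(series$date, control)
  X <- cbind(`(Intercept)` = 1, unclass(cb)[, , drop = FALSE], conf)
  keep <- attr(cb, "complete") & !is.na(series$deaths)
  y <- series$deaths[keep]
  X <- X[keep, , drop = FALSE]
  if (sum(y) == 0) {
    stop("degenerate data: all death counts are zero", call. = FALSE)
  }
  fit <- glm.fit(X, y, family = poisson(),
                 control = glm.control(epsilon = control$epsilon,
                                       maxit = control$maxit))
  if (!fit$converged) {
    stop(sprintf("IRLS did not converge in %d iterations (deviance %.6g)",
                 control$maxit, fit$deviance), call. = FALSE)
  }
  if (any(is.na(fit$coefficients))) {
    stop("degenerate design: aliased coefficients in the first-stage model",
         call. = FALSE)
  }
  mu <- fit$fitted.values
  p <- ncol(X)
  phi <- sum((y - mu)^2 / mu) / (length(y) - p)
  XtWX <- crossprod(X * sqrt(mu))
  vcov_full <- phi * chol2inv(chol(XtWX))
  cb_idx <- 1L + seq_len(ncol(cb))
  structure(list(
    coefficients = fit$coefficients,
    gamma = fit$coefficients[cb_idx],
    vcov_gamma = vcov_full[cb_idx, cb_idx, drop = FALSE],
    phi = phi,
    spec = spec,
    n_days = length(y),
    deviance = fit$deviance,
    iter = fit$iter,
    converged = fit$converged,
    location = attr(series, "location") %||% "loc",
    X = X, y = y
  ), class = "first_stage_fit")
}

#' Reduce a DLNM fit to the overall cumulative exposure-response curve
#'
#' Sums the fitted exposure-lag-response surface over the whole lag
#' window: `theta = M gamma`, `V(theta) = M V(gamma) M'`, where M adds up
#' the lag-basis contributions.  The curve is centered at `center` (the
#' location's median temperature by default), i.e. its predicted log
#' relative risk at the centering value is exactly zero; attribution
#' later re-centers at the minimum mortality temperature.
#'
#' @param fit a [fit_location()] result.
#' @param center centering temperature x0 (degrees C); default the median
#'   implied by the spec's 50th-percentile knot if present, otherwise the
#'   midpoint of the boundary knots.
#' @return an object of class `reduced_curve`: `coef` (theta), `vcov`,
#'   the basis definition, `center` and the location id.
#' @export
reduce_to_overall_cumulative <- function(fit, center = NULL) {
  stopifnot(inherits(fit, "first_stage_fit"))
  spec <- fit$spec
  M <- reduction_matrix(spec)
  theta <- drop(M %*% fit$gamma)
  V <- M %*% fit$vcov_gamma %*% t(M)
  if (is.null(center)) {
    i50 <- match(50, spec$var_percentiles)
    center <- if (!is.na(i50)) spec$var_knots[i50] else mean(spec$var_boundary)
  }
  structure(list(coef = theta, vcov = (V + t(V)) / 2,
                 var_knots = spec$var_knots,
                 var_boundary = spec$var_boundary,
                 var_percentiles = spec$var_percentiles,
                 center = center,
                 location = fit$location),
            class = "reduced_curve")
}

#' Construct a reduced curve directly from coefficients
#'
#' Used by the pooling stage (BLUPs share the first-stage basis) and by
#' tests that need curves with known coefficients.
#'
#' @param coef coefficient vector theta on the exposure basis.
#' @param vcov covariance of theta.
#' @param var_knots,var_boundary exposure-basis definition (degrees C).
#' @param center centering temperature.
#' @param location location id.
#' @param var_percentiles optional percentile positions of the knots.
#' @return a `reduced_curve`.
#' @export
reduced_curve <- function(coef, vcov, var_knots, var_boundary, center,
                          location = "loc", var_percentiles = NULL) {
  structure(list(coef = as.numeric(coef),
                 vcov = (as.matrix(vcov) + t(as.matrix(vcov))) / 2,
                 var_knots = as.numeric(var_knots),
                 var_boundary = as.numeric(var_boundary),
                 var_percentiles = var_percentiles,
                 center = center, location = location),
            class = "reduced_curve")
}

#' Exposure-basis matrix of a reduced curve, centered at its x0.
#' @noRd
curve_basis <- function(curve, x) {
  B <- ns_basis(x, curve$var_knots, curve$var_boundary)
  B0 <- ns_basis(curve$center, curve$var_knots, curve$var_boundary)
  sweep(B, 2, drop(B0), `-`)
}

#' Predict the overall cumulative curve on a temperature grid
#'
#' @param curve a `reduced_curve` (first-stage or BLUP).
#' @param x temperatures (degrees C); values beyond the boundary knots
#'   are extrapolated linearly (natural-spline tails) and flagged.
#' @param level confidence level of the pointwise normal interval.
#' @return data frame `x`, `logrr`, `se`, `rr`, `rr_low`, `rr_high`,
#'   `extrapolated`.
#' @export
predict_curve <- function(curve, x, level = 0.95) {
  stopifnot(inherits(curve, "reduced_curve"))
  D <- curve_basis(curve, x)
  logrr <- drop(D %*% curve$coef)
  se <- sqrt(pmax(rowSums((D %*% curve$vcov) * D), 0))
  z <- qnorm(1 - (1 - level) / 2)
  data.frame(x = x, logrr = logrr, se = se,
             rr = exp(logrr),
             rr_low = exp(logrr - z * se),
             rr_high = exp(logrr + z * se),
             extrapolated = x < curve$var_boundary[1] | x > curve$var_boundary[2])
}
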