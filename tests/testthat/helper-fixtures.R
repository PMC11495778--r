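# Small fixtures shared across test files; everything is generated in code.

# A short observed record with the default U-shaped association.
quick_series <- function(years = 3, seed = 101, assoc = true_association(),
                         base = baseline_params(), start = 2000) {
  cp <- climate_params(start_date = sprintf("%d-01-01", start),
                       end_date = sprintf("%d-12-31", start + years - 1))
  temps <- make_climate(cp, seed = seed)
  simulate_mortality(temps, assoc, base, seed = seed + 1)
}

# Project a target function onto a reduced-curve basis by least squares on
# a fine grid; returns a reduced_curve with (optionally zero) covariance.
curve_from_function <- function(f, var_knots = c(8, 14, 20),
                                var_boundary = c(-5, 32), center = 14,
                                vcov = NULL, location = "synthetic") {
  grid <- seq(var_boundary[1], var_boundary[2], length.out = 400)
  B <- ns_basis(grid, var_knots, var_boundary)
  theta <- qr.solve(cbind(1, B), f(grid))[-1]
  k <- length(theta)
  if (is.null(vcov)) vcov <- matrix(0, k, k)
  reduced_curve(theta, vcov, var_knots, var_boundary, center, location)
}

# Wald test of the cross-basis coefficient block of a first-stage fit.
crossbasis_wald_p <- function(fit) {
  stat <- drop(t(fit$gamma) %*% solve(fit$vcov_gamma, fit$gamma))
  stats::pchisq(stat, df = length(fit$gamma), lower.tail = FALSE)
}
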