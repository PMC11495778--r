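#' Meta-level structure of a synthetic multi-location study
#'
#' Per-location curve parameters (true MMT, cold curvature, heat
#' curvature) are drawn as `X_i beta_true + u_i`, `u_i ~ MVN(0,
#' psi_true)`, where the predictor row `X_i` holds an intercept and
#' standardised location mean temperature, temperature range and log GDP
#' per capita.  The defaults encode the stylised facts of multi-country
#' mortality panels: warmer locations acclimatise to a higher MMT, and
#' between-location heterogeneity remains after accounting for the
#' predictors.  Climate-zone labels are attached to the metadata as a
#' categorical descriptor (with true coefficient zero, so zone terms in a
#' fitted meta-regression estimate a null).
#'
#' @param beta_true 3 x 4 matrix mapping (intercept, z_avg_tmean, z_range,
#'   z_log_gdp) to the means of (true_mmt, cold_slope, heat_slope).
#' @param psi_true 3 x 3 between-location covariance of the parameters
#'   (symmetric positive semi-definite).
#' @param avg_tmean_mean,avg_tmean_sd distribution of location mean
#'   temperature (degrees C).
#' @param range_mean,range_sd distribution of the observed temperature
#'   range (degrees C).
#' @param log_gdp_mean,log_gdp_sd distribution of log GDP per capita.
#' @param zones climate-zone category labels.
#' @return an object of class `meta_structure`.
#' @export
meta_structure <- function(beta_true = rbind(
                             true_mmt   = c(18,    1.5,  0,    0.3),
                             cold_slope = c(8e-4,  0,    1e-4, -1e-4),
                             heat_slope = c(3e-3,  5e-4, 0,    0)),
                           psi_true = diag(c(1, 2e-4, 8e-4)^2),
                           avg_tmean_mean = 14, avg_tmean_sd = 5,
                           range_mean = 28, range_sd = 4,
                           log_gdp_mean = 10, log_gdp_sd = 0.6,
                           zones = c("temperate", "continental", "tropical")) {
  psi_true <- check_psd(psi_true, label = "psi_true")
  stopifnot(nrow(beta_true) == 3L, ncol(beta_true) == 4L,
            nrow(psi_true) == 3L)
  structure(list(beta_true = beta_true, psi_true = psi_true,
                 avg_tmean_mean = avg_tmean_mean, avg_tmean_sd = avg_tmean_sd,
                 range_mean = range_mean, range_sd = range_sd,
                 log_gdp_mean = log_gdp_mean, log_gdp_sd = log_gdp_sd,
                 zones = zones),
            class = "meta_structure")
}

#' Generate a multi-location study with known ground truth
#'
#' Draws location metadata, derives each location's true association from
#' the meta-level model, and simulates its daily temperature/mortality
#' series.  Each location uses an RNG substream hashed from the master
#' seed and its id, so the panel is reproducible location by location.
#' Curvature parameters are clipped below at `5e-5` per squared degree to
#' keep every drawn curve convex (U-shaped); the clip is part of the
#' generator's definition of its ground truth.
#'
#' @param meta a [meta_structure()].
#' @param n_locations number of locations, >= 2.
#' @param years_per_location length of each series in years, >= 4
#'   (matching the shortest series in multi-country mortality panels).
#' @param seed master seed.
#' @param n_regions number of geographic regions the locations are
#'   grouped into (round-robin assignment).
#' @param start_year first calendar year of the observed series.
#' @param base baseline mortality parameters shared across locations.
#' @return a list with elements `series` (named list of
#'   `location_series`), `metadata` (one row per location:
#'   `location,country,region,avg_tmean,range_tmean,gdp,zone`) and
#'   `truth` (per-location parameter matrix, residuals `u`, the
#'   associations, `beta_true`, `psi_true`).
#' @export
make_study <- function(meta = meta_structure(), n_locations = 10L,
                       years_per_location = 5L, seed = 1L,
                       n_regions = 4L, start_year = 2000L,
                       base = baseline_params()) {
  stopifnot(inherits(meta, "meta_structure"))
  if (n_locations < 2L) stop("n_locations must be >= 2", call. = FALSE)
  if (years_per_location < 4L) {
    stop("years_per_location must be >= 4 (shortest admissible series)",
         call. = FALSE)
  }
  ids <- sprintf("loc%03d", seq_len(n_locations))
  preds <- with_seed(substream_seed(seed, "study-predictors"), {
    data.frame(
      avg_tmean = rnorm(n_locations, meta$avg_tmean_mean, meta$avg_tmean_sd),
      range_tmean = pmax(rnorm(n_locations, meta$range_mean, meta$range_sd), 8),
      log_gdp = rnorm(n_locations, meta$log_gdp_mean, meta$log_gdp_sd),
      zone = sample(meta$zones, n_locations, replace = TRUE)
    )
  })
  X <- cbind(1,
             (preds$avg_tmean - meta$avg_tmean_mean) / meta$avg_tmean_sd,
             (preds$range_tmean - meta$range_mean) / meta$range_sd,
             (preds$log_gdp - meta$log_gdp_mean) / meta$log_gdp_sd)
  u <- with_seed(substream_seed(seed, "study-residuals"),
                 rmvnorm_psd(n_locations, c(0, 0, 0), meta$psi_true,
                             label = "psi_true"))
  params <- X %*% t(meta$beta_true) + u
  colnames(params) <- c("true_mmt", "cold_slope", "heat_slope")
  params[, "cold_slope"] <- pmax(params[, "cold_slope"], 5e-5)
  params[, "heat_slope"] <- pmax(params[, "heat_slope"], 5e-5)

  start_date <- as.Date(sprintf("%d-01-01", start_year))
  end_date <- as.Date(sprintf("%d-12-31", start_year + years_per_location - 1L))
  series <- vector("list", n_locations)
  assocs <- vector("list", n_locations)
  for (i in seq_len(n_locations)) {
    cp <- climate_params(
      mean_temp = preds$avg_tmean[i],
      seasonal_amplitude = preds$range_tmean[i] / 3.5,
      start_date = start_date, end_date = end_date
    )
    temps <- make_climate(cp, substream_seed(seed, c(ids[i], "climate")))
    assocs[[i]] <- true_association(true_mmt = params[i, "true_mmt"],
                                    cold_slope = params[i, "cold_slope"],
                                    heat_slope = params[i, "heat_slope"])
    series[[i]] <- simulate_mortality(temps, assocs[[i]], base,
                                      seed = substream_seed(seed, c(ids[i], "deaths")),
                                      location = ids[i])
  }
  names(series) <- names(assocs) <- ids
  metadata <- data.frame(
    location = ids,
    country = sprintf("country%02d", ((seq_len(n_locations) - 1L) %% max(2L, n_regions)) + 1L),
    region = sprintf("region%02d", ((seq_len(n_locations) - 1L) %% n_regions) + 1L),
    avg_tmean = preds$avg_tmean,
    range_tmean = preds$range_tmean,
    gdp = exp(preds$log_gdp),
    zone = preds$zone
  )
  list(series = series, metadata = metadata,
       truth = list(params = params, u = u, assoc = assocs,
                    beta_true = meta$beta_true, psi_true = meta$psi_true,
                    X = X))
}

#' Generate second-stage data with known pooled coefficients
#'
#' Draws location curve coefficients directly on the spline-coefficient
#' scale of the meta-regression: `theta_i = beta %*% x_i + u_i` with
#' `u_i ~ MVN(0, psi)`, observed with sampling error `e_i ~ MVN(0, S_i)`.
#' This gives an exactly known fixed-effect matrix `beta` and
#' between-location covariance `psi` for recovery tests of the pooling
#' stage, which the curve-parameter ground truth of [make_study()] cannot
#' provide (its parameters map nonlinearly onto the coefficient scale).
#'
#' @param X n x p design matrix (rows `x_i`).
#' @param beta k x p fixed-effect coefficient matrix.
#' @param psi k x k between-location covariance.
#' @param S a single k x k within-location covariance, or a list of n.
#' @param seed integer seed.
#' @return list with `theta_true` (n x k), `theta_hat` (n x k), `S`
#'   (list of n covariance matrices).
#' @export
make_meta_sample <- function(X, beta, psi, S, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  k <- nrow(as.matrix(beta))
  if (!is.list(S)) S <- rep(list(as.matrix(S)), n)
  stopifnot(length(S) == n)
  with_seed(seed, {
    u <- rmvnorm_psd(n, numeric(k), psi, label = "psi")
    theta_true <- X %*% t(beta) + u
    theta_hat <- theta_true
    for (i in seq_len(n)) {
      theta_hat[i, ] <- theta_true[i, ] +
        drop(rmvnorm_psd(1, numeric(k), S[[i]], label = "S"))
    }
    list(theta_true = theta_true, theta_hat = theta_hat, S = S)
  })
}
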