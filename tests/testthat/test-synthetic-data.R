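test_that("noise-free climate is the constant mean and generation is deterministic", {
  cp <- climate_params(mean_temp = 12, seasonal_amplitude = 0, ar1_coef = 0,
                       daily_sd = 0, start_date = "2000-01-01",
                       end_date = "2001-12-31")
  x <- make_climate(cp, seed = 1)
  expect_equal(nrow(x), 731L)  # includes the 2000 leap day
  expect_true(all(x$tmean == 12))

  cp2 <- climate_params()
  a <- make_climate(cp2, seed = 7)
  b <- make_climate(cp2, seed = 7)
  expect_identical(a, b)
  expect_false(all(a$tmean == make_climate(cp2, seed = 8)$tmean))
  expect_error(climate_params(start_date = "2005-01-01", end_date = "2004-01-01"),
               "date range")
  expect_error(climate_params(ar1_coef = 1), "ar1_coef")
})

test_that("deseasonalised residuals carry the configured AR(1) autocorrelation", {
  cp <- climate_params(ar1_coef = 0.7, start_date = "1985-01-01",
                       end_date = "2014-12-31")
  x <- make_climate(cp, seed = 3)
  doy <- as.POSIXlt(x$date)$yday + 1L
  seas <- cp$mean_temp + cp$seasonal_amplitude * cos(2 * pi * doy / 365.25 - cp$phase)
  res <- x$tmean - seas
  r1 <- cor(res[-1], res[-length(res)])
  expect_lt(abs(r1 - 0.7), 0.05)
  expect_lt(abs(mean(x$tmean) - cp$mean_temp), 0.5)
})

test_that("null association leaves counts at the baseline level", {
  assoc0 <- true_association(cold_slope = 0, heat_slope = 0)
  base <- baseline_params(seasonal_amplitude = 0, dow_effects = rep(0, 7),
                          overdispersion = 1)
  s <- quick_series(years = 6, seed = 21, assoc = assoc0, base = base)
  mu <- exp(base$intercept)
  se <- sqrt(mu * base$overdispersion / nrow(s))
  expect_lt(abs(mean(s$deaths) - mu), 3 * se)
})

test_that("a single hot day doubles that day's expected deaths under an immediate-lag surface", {
  # w(0) = 1: the surface acts on the same day only
  assoc <- true_association(true_mmt = 15, cold_slope = 0, heat_slope = 1,
                            weights = 1)
  base <- baseline_params(seasonal_amplitude = 0, dow_effects = rep(0, 7),
                          overdispersion = 1)
  n <- 400
  temps <- data.frame(date = seq(as.Date("2003-01-01"), by = "day",
                                 length.out = n),
                      tmean = rep(15, n))
  hot <- 15 + sqrt(log(2))   # f(T) = (T - 15)^2 = log 2
  temps$tmean[200] <- hot
  s <- simulate_mortality(temps, assoc, base, seed = 5)
  mu <- attr(s, "mu")
  expect_equal(mu[200] / mu[199], 2, tolerance = 1e-12)
})

test_that("gamma-Poisson mixture hits the requested variance/mean ratio", {
  assoc0 <- true_association(cold_slope = 0, heat_slope = 0)
  base <- baseline_params(seasonal_amplitude = 0, dow_effects = rep(0, 7),
                          overdispersion = 2)
  cp <- climate_params(seasonal_amplitude = 0, ar1_coef = 0, daily_sd = 0,
                       start_date = "1980-01-01", end_date = "2116-12-31")
  temps <- make_climate(cp, seed = 1)
  expect_gt(nrow(temps), 50000)
  s <- simulate_mortality(temps, assoc0, base, seed = 9)
  ratio <- var(s$deaths) / mean(s$deaths)
  expect_lt(abs(ratio - 2), 0.3)
  expect_error(baseline_params(overdispersion = 0.5), "overdispersion")
})

test_that("generator mean structure matches an independent day-by-day recomputation", {
  s <- quick_series(years = 2, seed = 31)
  assoc <- attr(s, "assoc"); base <- attr(s, "base")
  w <- assoc$weights; L <- length(w) - 1L
  lt <- as.POSIXlt(s$date)
  mu_loop <- numeric(nrow(s))
  for (t in seq_len(nrow(s))) {
    eta <- 0
    if (t > L) {
      for (l in 0:L) eta <- eta + w[l + 1] * eval_association(assoc, s$tmean[t - l])
    }
    bl <- base$intercept +
      base$seasonal_amplitude * cos(2 * pi * (lt$yday[t] + 1) / 365.25 - base$phase) +
      base$dow_effects[lt$wday[t] + 1]
    mu_loop[t] <- exp(bl + eta)
  }
  expect_lt(max(abs(mu_loop - attr(s, "mu"))), 1e-12)
  expect_identical(which(attr(s, "burnin")), 1:L)
})

test_that("make_study honours its degenerate, minimum-length and determinism contracts", {
  meta0 <- meta_structure(psi_true = matrix(0, 3, 3))
  st <- make_study(meta0, n_locations = 5, years_per_location = 4, seed = 2)
  expected <- st$truth$X %*% t(meta0$beta_true)
  expected[, 2:3] <- pmax(expected[, 2:3], 5e-5)
  expect_equal(unname(st$truth$params), unname(expected), tolerance = 1e-12)
  expect_true(all(st$truth$u == 0))

  expect_error(make_study(n_locations = 5, years_per_location = 3, seed = 1),
               ">= 4")
  expect_error(make_study(n_locations = 1, seed = 1), "n_locations")

  st2 <- make_study(meta0, n_locations = 5, years_per_location = 4, seed = 2)
  expect_identical(st$series, st2$series)
})

test_that("between-location residuals reproduce psi_true at Monte-Carlo scale", {
  meta <- meta_structure()
  st <- make_study(meta, n_locations = 40, years_per_location = 4, seed = 12)
  emp <- cov(st$truth$u)
  for (j in 1:3) {
    se <- meta$psi_true[j, j] * sqrt(2 / 39)
    expect_lt(abs(emp[j, j] - meta$psi_true[j, j]), 3 * se)
  }
})

test_that("pseudo-ESM series carry the configured bias and member count", {
  cp <- climate_params(start_date = "2000-01-01", end_date = "2009-12-31")
  obs <- make_climate(cp, seed = 4)
  cfg <- scenario_config("noLULCC", "ESM-X", n_members = 3, additive_bias = 2,
                         trend_per_decade = 0, variability_scale = 1)
  scen <- make_scenario_series(obs, cfg, seed = 6)
  expect_setequal(unique(scen$member), 1:3)
  m1 <- scen[scen$member == 1, ]
  common <- m1$date %in% obs$date
  diff <- mean(m1$tmean[common]) - mean(obs$tmean)
  # 3 SE of a mean difference of AR(1) residual series over ~3650 days
  se <- 2 * cp$daily_sd / sqrt(nrow(obs) * (1 - cp$ar1_coef) / (1 + cp$ar1_coef))
  expect_lt(abs(diff - 2), 3 * se)

  cfg_short <- scenario_config("noLULCC", "ESM-X", horizon_start = 2005,
                               horizon_end = 2099)
  expect_error(make_scenario_series(obs, cfg_short, seed = 1), "horizon")
  expect_error(scenario_config(n_members = 0), "n_members")
})
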