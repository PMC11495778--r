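make_obs <- function(seed = 71, years = c(2000, 2006)) {
  cp <- climate_params(start_date = sprintf("%d-01-01", years[1]),
                       end_date = sprintf("%d-12-31", years[2]))
  make_climate(cp, seed = seed)
}

test_that("calibrating a series against itself is the identity", {
  obs <- make_obs()
  cal <- calibrate_bias(obs, obs)
  expect_lt(max(abs(attr(cal, "offsets"))), 1e-12)
  expect_lt(max(abs(attr(cal, "scales") - 1)), 1e-12)
  expect_lt(max(abs(cal$tmean - obs$tmean)), 1e-12)
})

test_that("a constant model bias is corrected exactly and window means match observations", {
  obs <- make_obs()
  model <- obs
  model$tmean <- obs$tmean + 2
  cal <- calibrate_bias(model, obs)
  expect_lt(max(abs(attr(cal, "offsets") + 2)), 1e-12)
  expect_lt(max(abs(cal$tmean - obs$tmean)), 1e-12)

  # general case: window monthly means of the adjusted series equal the
  # observed monthly means to numerical precision
  cfg <- scenario_config("noLULCC", "ESM-T", n_members = 1, additive_bias = 1.4,
                         trend_per_decade = 0.3, variability_scale = 1.3)
  scen <- make_scenario_series(obs, cfg, seed = 72)
  cal2 <- calibrate_bias(scen[c("date", "tmean")], obs)
  w <- attr(cal2, "window")
  my <- as.integer(format(as.Date(cal2$date), "%Y"))
  mm <- as.integer(format(as.Date(cal2$date), "%m"))
  oy <- as.integer(format(as.Date(obs$date), "%Y"))
  om <- as.integer(format(as.Date(obs$date), "%m"))
  for (m in 1:12) {
    a <- mean(cal2$tmean[mm == m & my >= w[1] & my <= w[2]])
    b <- mean(obs$tmean[om == m & oy >= w[1] & oy <= w[2]])
    expect_lt(abs(a - b), 1e-9)
  }
})

test_that("calibration preserves the model's month-wise warming signal", {
  obs <- make_obs()
  cfg <- scenario_config("noLULCC", "ESM-T", n_members = 1, additive_bias = -2,
                         trend_per_decade = 0.5)
  scen <- make_scenario_series(obs, cfg, seed = 73)
  raw <- scen[c("date", "tmean")]
  cal <- calibrate_bias(raw, obs)
  w <- attr(cal, "window")
  yr <- as.integer(format(as.Date(raw$date), "%Y"))
  mo <- as.integer(format(as.Date(raw$date), "%m"))
  for (m in c(1, 4, 7, 10)) {
    future <- yr >= 2090 & mo == m
    win <- yr >= w[1] & yr <= w[2] & mo == m
    trend_before <- mean(raw$tmean[future]) - mean(raw$tmean[win])
    trend_after <- mean(cal$tmean[future]) - mean(cal$tmean[win])
    expect_lt(abs(trend_before - trend_after), 1e-9)
  }
})

test_that("calibration is idempotent and guards degenerate inputs", {
  obs <- make_obs()
  cfg <- scenario_config("noLULCC", "ESM-T", n_members = 1, additive_bias = 1,
                         variability_scale = 1.5)
  scen <- make_scenario_series(obs, cfg, seed = 74)
  cal <- calibrate_bias(scen[c("date", "tmean")], obs)
  cal2 <- calibrate_bias(cal, obs)
  expect_lt(max(abs(attr(cal2, "offsets"))), 1e-9)
  expect_lt(max(abs(attr(cal2, "scales") - 1)), 1e-9)

  flat <- obs; flat$tmean <- 10
  w12 <- testthat::capture_warnings(calibrate_bias(flat, obs))
  expect_true(all(grepl("zero model residual SD", w12)))
  expect_length(w12, 12L)
  late <- obs; late$date <- late$date + 40000
  expect_error(calibrate_bias(late, obs), "no overlap")
})

test_that("baseline mortality averages day-of-year profiles with leap-day fallback", {
  # constant record
  d1 <- data.frame(date = date_seq("2001-01-01", "2002-12-31"), deaths = 10)
  b1 <- baseline_mortality(d1, 1999, 2001)
  expect_true(all(b1$series$deaths == 10))
  # two observed years, counts 8 and 12 on the same day-of-year
  d2 <- data.frame(date = date_seq("2001-01-01", "2002-12-31"),
                   deaths = rep(c(8, 12), c(365, 365)))
  b2 <- baseline_mortality(d2, 2001, 2001)
  expect_true(all(b2$series$deaths == 10))
  # Feb-29 fallback: mean of the Feb-28 and Mar-1 profiles
  prof <- b2$profile
  expect_equal(unname(prof["02-29"]),
               unname((prof["02-28"] + prof["03-01"]) / 2))
  # bookkeeping: a projected non-leap year sums to the 365 day-of-year means
  y <- b2$series[format(b2$series$date, "%Y") == "2001", ]
  expect_lt(abs(sum(y$deaths) - sum(prof[names(prof) != "02-29"])), 1e-12)
  expect_error(baseline_mortality(d1[0, ]), "empty")
})

test_that("projected excess mortality is consistent with attribution and monotone in warming", {
  s <- quick_series(5, seed = 75)
  curve <- reduce_to_overall_cumulative(fit_location(s))
  mmt <- find_mmt(curve, s$tmean)
  base <- baseline_mortality(s, 2000, 2004)

  # identical climate: projecting the observed temperatures over the
  # observed window reproduces the attribution result on baseline deaths
  proj <- project_em(s[c("date", "tmean")], base, curve, mmt)
  an_direct <- attributable_numbers(s$tmean, base$series$deaths[
    match(as.Date(s$date), as.Date(base$series$date))], curve, mmt)
  expect_lt(max(abs(proj$an - as.numeric(an_direct))), 1e-12)
  expect_lt(max(abs(proj$an - (proj$an_cold + proj$an_heat))), 1e-12)

  # uniform warming raises heat EM and lowers cold EM
  warm <- s[c("date", "tmean")]; warm$tmean <- warm$tmean + 3
  proj_w <- project_em(warm, base, curve, mmt)
  expect_gte(sum(proj_w$an_heat), sum(proj$an_heat))
  expect_lte(sum(proj_w$an_cold), sum(proj$an_cold))

  # flat curve: no excess mortality anywhere
  flat <- curve; flat$coef[] <- 0
  expect_true(all(project_em(s[c("date", "tmean")], base, flat, mmt)$an == 0))
})

# Hand-built decade sums: 2 locations, 2 models, control + 1 scenario,
# 2 members, 2 decades; AN chosen so every aggregation step is checkable.
toy_sums <- function() {
  g <- expand.grid(location = c("A", "B"), model = c("M1", "M2"),
                   scenario = c("noLULCC", "sustainability"), member = 1:2,
                   decade = c("1980-1989", "2090-2099"),
                   stringsAsFactors = FALSE)
  set.seed(76)
  g$deaths <- ifelse(g$location == "A", 100, 300)
  g$an_cold <- round(runif(nrow(g), 2, 8), 3)
  g$an_heat <- round(runif(nrow(g), 1, 6), 3)
  g$an_total <- g$an_cold + g$an_heat
  g
}

test_that("aggregation computes death-weighted regional fractions and exact delta bookkeeping", {
  sums <- toy_sums()
  rmap <- data.frame(location = c("A", "B"), region = c("R1", "R1"))
  agg <- aggregate_projection(sums, rmap)

  # control deltas vanish in the reference decade
  bm <- agg$by_member
  ref <- bm[bm$scenario == "noLULCC" & bm$decade == "1980-1989", ]
  expect_lt(max(abs(ref$delta_pp)), 1e-12)

  # delta bookkeeping: d(sust - ctrl) + d(ctrl - hist) = sust - hist
  for (i in seq_len(nrow(bm))) {
    if (bm$scenario[i] != "sustainability" || bm$decade[i] == "1980-1989") next
    same <- function(sc, dec) bm$fraction_pct[bm$location == bm$location[i] &
      bm$model == bm$model[i] & bm$member == bm$member[i] &
      bm$scenario == sc & bm$decade == dec & bm$component == bm$component[i]]
    d_ctrl <- bm$delta_pp[bm$location == bm$location[i] & bm$model == bm$model[i] &
      bm$member == bm$member[i] & bm$scenario == "noLULCC" &
      bm$decade == bm$decade[i] & bm$component == bm$component[i]]
    lhs <- bm$delta_pp[i] + d_ctrl
    rhs <- same("sustainability", bm$decade[i]) - same("noLULCC", "1980-1989")
    expect_lt(abs(lhs - rhs), 1e-12)
  }

  # death-weighted regional pooling: (5,100) & (15,300) in every cell must
  # give 5% everywhere, not the unweighted mean of 5% and 15% (= 10%)
  wsums <- sums
  wsums$an_cold <- ifelse(wsums$location == "A", 5, 15)
  wsums$an_heat <- 0
  wsums$an_total <- wsums$an_cold
  wsums$deaths <- ifelse(wsums$location == "A", 100, 300)
  agg2 <- aggregate_projection(wsums, rmap)
  reg_total <- agg2$regional[agg2$regional$component == "total", ]
  expect_lt(max(abs(reg_total$fraction_pct - 5)), 1e-12)

  # single model & member: multimodel mean equals that run's value
  solo <- sums[sums$model == "M1" & sums$member == 1, ]
  agg3 <- aggregate_projection(solo, rmap)
  merged <- merge(agg3$by_member, agg3$multimodel,
                  by = c("location", "scenario", "decade", "component"))
  expect_lt(max(abs(merged$fraction_pct.x - merged$fraction_pct.y)), 1e-12)

  # scenario identical to the control: all its deltas vanish
  dup <- sums[sums$scenario == "noLULCC", ]
  clone <- dup; clone$scenario <- "sustainability"
  agg4 <- aggregate_projection(rbind(dup, clone), rmap)
  sust <- agg4$by_member[agg4$by_member$scenario == "sustainability", ]
  expect_lt(max(abs(sust$delta_pp)), 1e-12)

  # missing control cells are reported
  broken <- sums[!(sums$scenario == "noLULCC" & sums$model == "M2"), ]
  expect_error(aggregate_projection(broken, rmap), "missing control cells")
  expect_error(aggregate_projection(sums, data.frame(location = "A",
                                                     region = "R1")),
               "missing from the region map")
})

test_that("projection-period Monte-Carlo intervals bracket the point fractions", {
  s <- quick_series(5, seed = 77)
  curve <- reduce_to_overall_cumulative(fit_location(s))
  mmt <- find_mmt(curve, s$tmean)
  base <- baseline_mortality(s, 2000, 2010)
  cfg <- scenario_config("noLULCC", "ESM-T", n_members = 1,
                         additive_bias = 0.5, trend_per_decade = 0.4,
                         horizon_start = 2000, horizon_end = 2010)
  scen <- make_scenario_series(s, cfg, seed = 78)
  cal <- calibrate_bias(scen[c("date", "tmean")], s, window = c(2000, 2004))
  ci <- project_decade_ci(cal, base, curve, mmt, decades = "2000-2009",
                          n_samples = 200, seed = 79)
  daily <- project_em(cal, base, curve, mmt)
  daily$decade <- "2000-2009"
  for (cmp in c("cold", "heat", "total")) {
    an_cmp <- switch(cmp, cold = sum(daily$an_cold), heat = sum(daily$an_heat),
                     total = sum(daily$an))
    frac <- 100 * an_cmp / sum(daily$deaths)
    row <- ci[ci$component == cmp, ]
    expect_lte(row$ci_low, frac + 1e-9)
    expect_gte(row$ci_high, frac - 1e-9)
  }
})
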