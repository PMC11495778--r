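test_that("meta-design standardisation round-trips and rank problems are caught", {
  md <- data.frame(location = paste0("l", 1:8),
                   avg_tmean = c(10, 12, 15, 18, 20, 9, 14, 22),
                   range_tmean = c(25, 30, 28, 22, 26, 31, 24, 27),
                   gdp = exp(seq(9, 10.4, length.out = 8)),
                   zone = rep(c("temperate", "tropical"), 4))
  d <- build_meta_design(md)
  # reproducing the standardisation from the recorded centers/scales
  z <- (log(md$gdp) - d$centers["log_gdp"]) / d$scales["log_gdp"]
  expect_lt(max(abs(z - d$X[, "log_gdp"])), 1e-12)
  expect_equal(colnames(d$X)[1], "intercept")

  md_flat <- md; md_flat$avg_tmean <- 5
  expect_error(build_meta_design(md_flat), "avg_tmean")
  md_onezone <- md; md_onezone$zone <- "temperate"
  expect_warning(d1 <- build_meta_design(md_onezone), "zone block dropped")
  expect_false(any(grepl("zone", colnames(d1$X))))
  md_na <- md; md_na$gdp[2] <- NA
  expect_error(build_meta_design(md_na), "missing")
})

test_that("univariate REML matches the DerSimonian-REML oracle and balanced means", {
  set.seed(8)
  y <- rnorm(25, 0.4, 0.6)
  v <- runif(25, 0.05, 0.25)
  curves <- lapply(seq_along(y), function(i)
    reduced_curve(y[i], matrix(v[i]), 15, c(0, 30), 15, paste0("u", i)))
  mf <- fit_meta(curves, matrix(1, 25, 1))
  or <- metafor::rma(yi = y, vi = v, method = "REML",
                     control = list(threshold = 1e-12))
  expect_lt(abs(mf$psi[1, 1] - or$tau2), 1e-6)
  expect_lt(abs(mf$beta[1, 1] - as.numeric(or$beta)), 1e-6)
  expect_lt(abs(sqrt(mf$vcov_beta[1, 1]) - or$se), 1e-6)

  # equal S_i and intercept-only design: pooled estimate = arithmetic mean
  curves_eq <- lapply(seq_along(y), function(i)
    reduced_curve(y[i], matrix(0.1), 15, c(0, 30), 15, paste0("e", i)))
  mf_eq <- fit_meta(curves_eq, matrix(1, 25, 1))
  expect_equal(mf_eq$beta[1, 1], mean(y), tolerance = 1e-8)
})

test_that("constraining Psi to zero reproduces fixed-effect GLS", {
  set.seed(9)
  n <- 12
  X <- cbind(1, rnorm(n))
  y <- drop(X %*% c(1, 0.5)) + rnorm(n, 0, 0.3)
  v <- runif(n, 0.02, 0.2)
  curves <- lapply(seq_len(n), function(i)
    reduced_curve(y[i], matrix(v[i]), 15, c(0, 30), 15, paste0("f", i)))
  mf <- fit_meta(curves, X, method = "fixed")
  W <- diag(1 / v)
  beta_gls <- solve(t(X) %*% W %*% X, t(X) %*% W %*% y)
  expect_equal(unname(drop(mf$beta)), unname(drop(beta_gls)), tolerance = 1e-10)
  expect_true(all(mf$psi == 0))
})

test_that("REML restricted likelihood at the optimum dominates boundary and start values", {
  set.seed(10)
  X <- cbind(1, rnorm(30))
  sam <- make_meta_sample(X, rbind(c(0.3, 0.2), c(-0.2, 0.4)),
                          diag(c(0.05, 0.08)), diag(0.06, 2), seed = 11)
  curves <- lapply(1:30, function(i)
    reduced_curve(sam$theta_hat[i, ], sam$S[[i]], c(10, 15, 20), c(0, 30), 15,
                  paste0("g", i)))
  mf <- fit_meta(curves, X)
  ll_opt <- meta_logLik(mf, mf$psi)
  expect_gte(ll_opt + 1e-6, meta_logLik(mf, matrix(0, 2, 2)))
  mom <- cov(sam$theta_hat) - diag(0.06, 2)
  mom <- diag(pmax(diag(mom), 1e-4))
  expect_gte(ll_opt + 1e-6, meta_logLik(mf, mom))
})

test_that("BLUPs obey their limiting forms and the toy closed form", {
  set.seed(12)
  X <- cbind(1, rnorm(10))
  beta <- rbind(c(0.5, 0.1), c(0, -0.3))
  sam <- make_meta_sample(X, beta, diag(c(0.05, 0.05)), diag(1e-10, 2), seed = 13)
  curves <- lapply(1:10, function(i)
    reduced_curve(sam$theta_hat[i, ], diag(1e-10, 2), c(10, 15, 20), c(0, 30),
                  15, paste0("h", i)))
  # no-shrinkage limit: S_i -> 0 pulls the BLUP onto the first-stage estimate
  mf <- fit_meta(curves, X)
  bl <- compute_blups(mf, curves)
  for (i in 1:10) {
    expect_equal(unname(bl[[i]]$coef), unname(sam$theta_hat[i, ]),
                 tolerance = 1e-4)
  }
  # full-shrinkage limit: Psi = 0 pulls every BLUP onto the meta prediction
  mf0 <- mf; mf0$psi <- matrix(0, 2, 2)
  bl0 <- compute_blups(mf0, curves)
  for (i in 1:10) {
    expect_equal(unname(bl0[[i]]$coef), unname(drop(mf$beta %*% X[i, ])),
                 tolerance = 1e-10)
  }
  # 1-D toy: S = 1, Psi = 1, theta_hat = 2, mean 0 -> BLUP = 1
  toy_curves <- list(reduced_curve(2, matrix(1), 15, c(0, 30), 15, "toy"))
  toy_fit <- structure(list(beta = matrix(0, 1, 1),
                            vcov_beta = matrix(0, 1, 1),
                            psi = matrix(1, 1, 1), k = 1L, p = 1L,
                            X = matrix(1, 1, 1), Y = matrix(2, 1, 1),
                            S = list(matrix(1))), class = "meta_fit")
  expect_equal(compute_blups(toy_fit, toy_curves)[[1]]$coef, 1,
               tolerance = 1e-12)
})

test_that("univariate BLUPs always lie between the estimate and the meta prediction", {
  set.seed(14)
  for (rep in 1:5) {
    n <- 15
    X <- cbind(1, rnorm(n))
    sam <- make_meta_sample(X, matrix(c(0.5, 0.3), 1), matrix(0.04),
                            lapply(runif(n, 0.01, 0.3), matrix), seed = rep)
    curves <- lapply(1:n, function(i)
      reduced_curve(sam$theta_hat[i, ], sam$S[[i]], 15, c(0, 30), 15,
                    paste0("s", i)))
    mf <- fit_meta(curves, X)
    bl <- compute_blups(mf, curves)
    for (i in 1:n) {
      pred <- drop(mf$beta %*% X[i, ])
      lo <- min(sam$theta_hat[i, 1], pred) - 1e-10
      hi <- max(sam$theta_hat[i, 1], pred) + 1e-10
      expect_true(bl[[i]]$coef >= lo && bl[[i]]$coef <= hi)
    }
  }
})

test_that("pooling rejects inconsistent inputs", {
  curves <- lapply(1:6, function(i)
    reduced_curve(c(1, 2), diag(0.1, 2), c(10, 15, 20), c(0, 30), 15,
                  paste0("m", i)))
  mixed <- c(curves[1:5], list(reduced_curve(1, matrix(0.1), 15, c(0, 30), 15, "odd")))
  expect_error(fit_meta(mixed, matrix(1, 6, 1)), "basis")
  expect_error(fit_meta(curves[1:2], matrix(1, 2, 1)), "locations")
})

test_that("BLUP curves beat first-stage curves in mean squared error on full synthetic studies", {
  # end-to-end shrinkage gain, measured against the known true curves on a
  # common temperature grid (3 replicate studies of 12 locations)
  mse_fs <- mse_bl <- 0
  for (rep in 1:3) {
    st <- make_study(n_locations = 12, years_per_location = 4,
                     seed = 700 + rep, n_regions = 3)
    curves <- lapply(st$series, function(s) reduce_to_overall_cumulative(fit_location(s)))
    design <- build_meta_design(st$metadata, predictors = "avg_tmean",
                                include_zone = FALSE)
    mf <- fit_meta(curves, design)
    bl <- compute_blups(mf, curves)
    for (i in seq_along(curves)) {
      assoc <- st$truth$assoc[[i]]
      temps <- st$series[[i]]$tmean
      grid <- as.numeric(quantile(temps, seq(0.05, 0.95, length.out = 25)))
      truth <- eval_association(assoc, grid) - eval_association(assoc, curves[[i]]$center)
      err_fs <- predict_curve(curves[[i]], grid)$logrr - truth
      err_bl <- predict_curve(bl[[i]], grid)$logrr - truth
      mse_fs <- mse_fs + mean(err_fs^2)
      mse_bl <- mse_bl + mean(err_bl^2)
    }
  }
  expect_lt(mse_bl, mse_fs)
})
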