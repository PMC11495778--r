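#' Build the meta-regression design matrix
#'
#' One row per location: intercept, standardised mean observed
#' temperature, standardised observed temperature range, standardised log
#' GDP per capita, and one-hot climate-zone indicators (first level as
#' reference).  Continuous predictors are centered and scaled; the
#' centers and scales are recorded so the design can be reproduced from
#' the emitted metadata.
#'
#' @param metadata data frame with columns `location`, `avg_tmean`,
#'   `range_tmean`, `gdp`, `zone`.
#' @param predictors continuous predictors to include, a subset of
#'   `c("avg_tmean", "range_tmean", "log_gdp")`; small studies may need
#'   a reduced design to keep locations >= p + 2.
#' @param include_zone whether to add the one-hot climate-zone block.
#' @return an object of class `meta_design`: `X`, `locations`, `centers`,
#'   `scales`.
#' @export
build_meta_design <- function(metadata,
                              predictors = c("avg_tmean", "range_tmean",
                                             "log_gdp"),
                              include_zone = TRUE) {
  need <- c("location", "avg_tmean", "range_tmean", "gdp", "zone")
  stopifnot(all(need %in% names(metadata)))
  predictors <- match.arg(predictors, c("avg_tmean", "range_tmean", "log_gdp"),
                          several.ok = TRUE)
  cont <- cbind(avg_tmean = metadata$avg_tmean,
                range_tmean = metadata$range_tmean,
                log_gdp = log(metadata$gdp))[, predictors, drop = FALSE]
  if (anyNA(cont) || anyNA(metadata$zone)) {
    stop("missing meta-predictor values", call. = FALSE)
  }
  centers <- colMeans(cont)
  scales <- apply(cont, 2, sd)
  if (any(scales == 0)) {
    stop(sprintf("collinear meta-predictors (no variation): %s",
                 paste(colnames(cont)[scales == 0], collapse = ", ")),
         call. = FALSE)
  }
  Z <- sweep(sweep(cont, 2, centers), 2, scales, `/`)
  zones <- sort(unique(as.character(metadata$zone)))
  X <- cbind(intercept = 1, Z)
  if (include_zone) {
    if (length(zones) > 1L) {
      for (z in zones[-1]) {
        X <- cbind(X, as.numeric(metadata$zone == z))
        colnames(X)[ncol(X)] <- paste0("zone_", z)
      }
    } else {
      warning("single climate-zone category; zone block dropped from the design")
    }
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop(sprintf("rank-deficient meta-design; collinear columns: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  structure(list(X = X, locations = as.character(metadata$location),
                 centers = centers, scales = scales),
            class = "meta_design")
}

#' Assemble outcome matrix and covariances from reduced curves.
#' @noRd
stack_curves <- function(curves) {
  stopifnot(length(curves) >= 1L)
  ref <- curves[[1]]
  for (cv in curves) {
    stopifnot(inherits(cv, "reduced_curve"))
    if (length(cv$coef) != length(ref$coef)) {
      stop("curves mix basis descriptors (different dimensions)", call. = FALSE)
    }
  }
  Y <- do.call(rbind, lapply(curves, function(cv) as.numeric(cv$coef)))
  S <- lapply(curves, function(cv) cv$vcov)
  list(Y = Y, S = S, ids = vapply(curves, function(cv) cv$location, ""))
}

#' Log-Cholesky parameterisation helpers.
#' @noRd
par_to_psi <- function(par, k) {
  L <- matrix(0, k, k)
  L[lower.tri(L, diag = TRUE)] <- par
  diag(L) <- exp(diag(L))
  tcrossprod(L)
}

#' @noRd
psi_to_par <- function(psi) {
  k <- nrow(psi)
  L <- t(chol(psi + diag(1e-10 * max(diag(psi), 1e-8), k)))
  diag(L) <- log(diag(L))
  L[lower.tri(L, diag = TRUE)]
}

#' GLS profile of the restricted likelihood at a given Psi.
#' @noRd
meta_profile <- function(Y, S, X, psi) {
  n <- nrow(Y); k <- ncol(Y); p <- ncol(X)
  A <- matrix(0, k * p, k * p)
  bv <- numeric(k * p)
  W <- vector("list", n)
  ldet_sum <- 0
  for (i in seq_len(n)) {
    Sig <- S[[i]] + psi
    U <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(U)) return(NULL)
    W[[i]] <- chol2inv(U)
    ldet_sum <- ldet_sum + 2 * sum(log(diag(U)))
    A <- A + kronecker(tcrossprod(X[i, ]), W[[i]])
    bv <- bv + kronecker(X[i, ], W[[i]] %*% Y[i, ])
  }
  Ua <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(Ua)) return(NULL)
  beta_vec <- drop(chol2inv(Ua) %*% bv)
  Beta <- matrix(beta_vec, k, p)
  rss <- 0
  for (i in seq_len(n)) {
    r <- Y[i, ] - drop(Beta %*% X[i, ])
    rss <- rss + drop(crossprod(r, W[[i]] %*% r))
  }
  neg2rl <- ldet_sum + 2 * sum(log(diag(Ua))) + rss
  list(Beta = Beta, vcov_beta = chol2inv(Ua), neg2rl = neg2rl, W = W)
}

#' Method-of-moments starting value for Psi.
#' @noRd
psi_start <- function(Y, S) {
  k <- ncol(Y)
  Sbar <- Reduce(`+`, S) / length(S)
  P0 <- cov(Y) - Sbar
  e <- eigen((P0 + t(P0)) / 2, symmetric = TRUE)
  floor_val <- 1e-4 * max(mean(diag(Sbar)), 1e-8)
  e$vectors %*% (pmax(e$values, floor_val) * t(e$vectors))
}

#' Pool reduced curves with a multivariate random-effects meta-regression
#'
#' Fits `theta_hat_i ~ MVN(Beta x_i, S_i + Psi)` where `S_i` is the
#' location's first-stage covariance and `Psi` an unstructured
#' between-location covariance.  `Beta` is profiled out by generalised
#' least squares; `Psi` maximises the restricted (REML) likelihood over a
#' log-Cholesky parameterisation by quasi-Newton ascent started from a
#' method-of-moments value.  With `method = "fixed"`, `Psi` is held at
#' zero and the fit is the fixed-effect GLS estimate.
#'
#' @param curves list of `reduced_curve` objects sharing one basis.
#' @param design a [build_meta_design()] result (or a bare matrix).
#' @param method `"reml"` (default) or `"fixed"`.
#' @param reltol convergence tolerance on the restricted likelihood.
#' @return an object of class `meta_fit`: `beta` (k x p), `vcov_beta`
#'   (kp x kp, column-stacked), `psi`, `logLik_restricted`, convergence
#'   info, and the stacked data for downstream BLUPs.
#' @export
fit_meta <- function(curves, design, method = c("reml", "fixed"),
                     reltol = 1e-10) {
  method <- match.arg(method)
  st <- stack_curves(curves)
  X <- if (inherits(design, "meta_design")) design$X else as.matrix(design)
  if (nrow(X) != nrow(st$Y)) {
    stop("design and curve list have different numbers of locations", call. = FALSE)
  }
  k <- ncol(st$Y); p <- ncol(X)
  if (nrow(st$Y) < p + 2L) {
    stop("need at least p + 2 locations to fit the meta-regression", call. = FALSE)
  }
  if (method == "fixed") {
    prof <- meta_profile(st$Y, st$S, X, matrix(0, k, k))
    if (is.null(prof)) stop("singular GLS system in fixed-effect fit", call. = FALSE)
    psi <- matrix(0, k, k)
    conv <- list(convergence = 0L, iterations = 0L)
  } else {
    obj <- function(par) {
      prof <- meta_profile(st$Y, st$S, X, par_to_psi(par, k))
      if (is.null(prof)) return(1e12)
      prof$neg2rl
    }
    par0 <- psi_to_par(psi_start(st$Y, st$S))
    opt <- optim(par0, obj, method = "BFGS",
                 control = list(reltol = reltol, maxit = 500L))
    if (opt$convergence != 0 && opt$convergence != 1) {
      stop(sprintf("meta-regression REML did not converge (code %d): %s",
                   opt$convergence, opt$message %||% ""), call. = FALSE)
    }
    psi <- par_to_psi(opt$par, k)
    prof <- meta_profile(st$Y, st$S, X, psi)
    conv <- list(convergence = opt$convergence,
                 iterations = opt$counts[["function"]])
  }
  structure(list(beta = prof$Beta, vcov_beta = prof$vcov_beta,
                 psi = (psi + t(psi)) / 2,
                 logLik_restricted = -prof$neg2rl / 2,
                 method = method, convergence = conv,
                 k = k, p = p, X = X, Y = st$Y, S = st$S,
                 locations = st$ids,
                 predictors = colnames(X)),
            class = "meta_fit")
}

#' Restricted log-likelihood of a meta fit at an arbitrary Psi.
#'
#' Exposed for diagnostics and likelihood-comparison tests.
#'
#' @param fit a [fit_meta()] result.
#' @param psi a k x k covariance matrix.
#' @return the restricted log-likelihood (up to the REML constant).
#' @export
meta_logLik <- function(fit, psi) {
  prof <- meta_profile(fit$Y, fit$S, fit$X, psi)
  if (is.null(prof)) return(-Inf)
  -prof$neg2rl / 2
}

#' Best linear unbiased predictions of the location curves
#'
#' Shrinks each first-stage curve towards its meta-regression prediction
#' in proportion to its sampling uncertainty: `theta_blup_i = Beta x_i +
#' Psi (S_i + Psi)^-1 (theta_hat_i - Beta x_i)`.  The BLUP covariance is
#' the conditional covariance `Psi - Psi (S_i + Psi)^-1 Psi` plus the
#' shrinkage-propagated uncertainty of the fixed-effect prediction;
#' uncertainty in `Psi` itself is ignored (the empirical-Bayes
#' convention).
#'
#' @param fit a [fit_meta()] result.
#' @param curves the list of `reduced_curve` objects that was pooled
#'   (supplies the basis definition of the returned curves).
#' @return a named list of `reduced_curve` objects (class also `blup`).
#' @export
compute_blups <- function(fit, curves) {
  stopifnot(inherits(fit, "meta_fit"))
  st <- stack_curves(curves)
  k <- fit$k
  n <- nrow(fit$X)
  out <- vector("list", n)
  Ik <- diag(k)
  for (i in seq_len(n)) {
    Sig <- st$S[[i]] + fit$psi
    Wi <- tryCatch(chol2inv(chol(Sig)), error = function(e)
      stop("singular S_i + Psi in BLUP computation", call. = FALSE))
    G <- fit$psi %*% Wi
    xb <- drop(fit$beta %*% fit$X[i, ])
    theta <- xb + drop(G %*% (st$Y[i, ] - xb))
    Zi <- kronecker(matrix(fit$X[i, ], 1), Ik)
    Ai <- (Ik - G) %*% Zi
    V <- fit$psi - G %*% fit$psi + Ai %*% fit$vcov_beta %*% t(Ai)
    cv <- curves[[i]]
    out[[i]] <- reduced_curve(theta, (V + t(V)) / 2,
                              var_knots = cv$var_knots,
                              var_boundary = cv$var_boundary,
                              center = cv$center,
                              location = cv$location,
                              var_percentiles = cv$var_percentiles)
    class(out[[i]]) <- c("blup", "reduced_curve")
  }
  names(out) <- st$ids
  out
}
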