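#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible substream seed from a master seed and a string id.
#'
#' All stochastic stages share one master seed; per-location and per-member
#' streams are derived by hashing the id so that adding or reordering units
#' does not perturb the streams of the others.  The result stays below 2^31.
#'
#' @param seed integer master seed.
#' @param id character or integer identifier of the substream.
#' @return an integer seed.
#' @export
substream_seed <- function(seed, id) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  chars <- utf8ToInt(paste(as.character(id), collapse = "/"))
  h <- as.double(seed) %% 2147483647
  for (c in chars) {
    h <- (h * 131 + c) %% 2147483647
  }
  as.integer(h)
}

#' Evaluate an expression with a local, restorable RNG seed.
#' @noRd
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

#' Days in a sequence of calendar dates.
#' @noRd
date_seq <- function(start_date, end_date) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (is.na(start_date) || is.na(end_date)) {
    stop("invalid date range: dates must be parseable as ISO-8601", call. = FALSE)
  }
  if (end_date < start_date) {
    stop("invalid date range: end_date is before start_date", call. = FALSE)
  }
  seq(start_date, end_date, by = "day")
}

#' Month-day key ("02-29" style) used for day-of-year profiles.
#' @noRd
monthday <- function(dates) format(as.Date(dates), "%m-%d")

#' Symmetrise and check positive semi-definiteness.
#'
#' @param V a square matrix.
#' @param tol relative tolerance on the most negative eigenvalue.
#' @param label name used in error messages.
#' @return the symmetrised matrix with tiny negative eigenvalues clipped.
#' @noRd
check_psd <- function(V, tol = 1e-8, label = "covariance") {
  V <- (V + t(V)) / 2
  e <- eigen(V, symmetric = TRUE)
  scale <- max(abs(e$values), 1e-300)
  if (min(e$values) < -tol * scale) {
    stop(sprintf("%s matrix is not positive semi-definite", label), call. = FALSE)
  }
  vals <- pmax(e$values, 0)
  V <- e$vectors %*% (vals * t(e$vectors))
  (V + t(V)) / 2
}

#' Draw from a multivariate normal with a PSD covariance (eigen factor).
#' @noRd
rmvnorm_psd <- function(n, mean, V, label = "covariance") {
  V <- check_psd(V, label = label)
  k <- length(mean)
  e <- eigen(V, symmetric = TRUE)
  A <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), k)
  z <- matrix(rnorm(n * k), n, k)
  sweep(z %*% t(A), 2, mean, `+`)
}

#' Decade label ("1980-1989") for a vector of dates.
#' @noRd
decade_of <- function(dates) {
  y <- as.integer(format(as.Date(dates), "%Y"))
  d0 <- (y %/% 10L) * 10L
  sprintf("%d-%d", d0, d0 + 9L)
}
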