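#' Natural cubic spline basis with explicit knots
#'
#' Thin wrapper around [splines::ns()] that fixes the interior and boundary
#' knots explicitly, so that the same basis can be rebuilt bit-identically
#' for new temperature values (prediction, centering, curve reduction).
#' The basis is linear beyond the boundary knots, which is what makes
#' extrapolation into unobserved temperature tails well behaved.
#'
#' @param x numeric vector of evaluation points (degrees C in this package).
#' @param knots strictly increasing interior knots, all inside `boundary`.
#' @param boundary length-2 vector of boundary knots.
#' @return an `n x (length(knots) + 1)` numeric matrix.
#' @export
ns_basis <- function(x, knots, boundary) {
  if (length(boundary) != 2L || boundary[1] >= boundary[2]) {
    stop("boundary must be an increasing pair", call. = FALSE)
  }
  knots <- as.numeric(knots)
  if (is.unsorted(knots, strictly = TRUE)) {
    stop("knots must be strictly increasing", call. = FALSE)
  }
  if (length(knots) && (min(knots) <= boundary[1] || max(knots) >= boundary[2])) {
    stop("knots must lie strictly inside the boundary knots", call. = FALSE)
  }
  b <- splines::ns(x, knots = knots, Boundary.knots = boundary, intercept = FALSE)
  m <- matrix(as.numeric(b), nrow = length(x))
  colnames(m) <- paste0("b", seq_len(ncol(m)))
  m
}

#' Lag basis: natural cubic spline of lag with an intercept column
#'
#' Evaluated on the integer lags `0:L`.  With `L = 0` the lag dimension
#' collapses to the intercept column alone, so the cross-basis reduces to
#' the exposure basis of the same-day temperature.
#'
#' @param max_lag maximum lag L in days.
#' @param lag_knots interior knots on the lag scale, strictly inside (0, L).
#' @return an `(L + 1) x df_lag` matrix, first column identically 1.
#' @export
lag_basis <- function(max_lag, lag_knots = default_lag_knots(max_lag)) {
  if (max_lag < 0) stop("max_lag must be >= 0", call. = FALSE)
  lags <- 0:max_lag
  if (max_lag == 0 || length(lag_knots) == 0L && max_lag < 2) {
    m <- matrix(1, length(lags), 1L)
  } else {
    m <- cbind(1, ns_basis(lags, knots = lag_knots, boundary = c(0, max_lag)))
  }
  colnames(m) <- paste0("l", seq_len(ncol(m)))
  m
}

#' Default lag knots: equally spaced on the log(lag + 1) scale
#'
#' The log placement concentrates flexibility at short lags, where acute
#' heat effects act, while still allowing the slow cold response to build
#' up over weeks.
#'
#' @param max_lag maximum lag in days.
#' @param n_knots number of interior knots (default 3, giving 5 lag df
#'   together with the intercept for the conventional 21-day window).
#' @return numeric vector of interior lag knots.
#' @export
default_lag_knots <- function(max_lag, n_knots = 3L) {
  if (max_lag < 2 || n_knots < 1L) return(numeric(0))
  u <- seq(log(1), log(max_lag + 1), length.out = n_knots + 2L)
  exp(u[-c(1L, n_knots + 2L)]) - 1
}
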