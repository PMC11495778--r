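#' Specification of a DLNM cross-basis
#'
#' Defines the two marginal bases of a distributed lag nonlinear model:
#' a natural cubic spline of temperature with knots placed at percentiles
#' of the location's own temperature distribution, and a natural cubic
#' spline of lag (with intercept) over a window of `max_lag` days.  The
#' defaults follow the conventions of the multi-country two-stage
#' framework: exposure knots at the 10th/50th/90th percentiles, boundary
#' knots at the observed minimum/maximum, a 21-day lag window, and lag
#' knots equally spaced on the log scale.  Percentiles use linear
#' interpolation (`type = 7`), which matters because the minimum mortality
#' temperature is later reported on the same percentile scale.
#'
#' @param var_percentiles percentiles (in (0, 100)) of the temperature
#'   distribution at which exposure knots are placed.
#' @param max_lag maximum lag L in days.
#' @param lag_knots interior knots for the lag spline; default log-spaced.
#' @return an object of class `cross_basis_spec`.
#' @export
cross_basis_spec <- function(var_percentiles = c(10, 50, 90),
                             max_lag = 21L,
                             lag_knots = default_lag_knots(max_lag)) {
  if (max_lag < 0) stop("max_lag must be >= 0", call. = FALSE)
  if (length(var_percentiles) < 1L ||
      any(var_percentiles <= 0 | var_percentiles >= 100)) {
    stop("var_percentiles must lie strictly between 0 and 100", call. = FALSE)
  }
  if (is.unsorted(var_percentiles, strictly = TRUE)) {
    stop("var_percentiles must be strictly increasing", call. = FALSE)
  }
  structure(
    list(var_percentiles = as.numeric(var_percentiles),
         max_lag = as.integer(max_lag),
         lag_knots = as.numeric(lag_knots)),
    class = "cross_basis_spec"
  )
}

#' Resolve a cross-basis spec against an observed temperature series
#'
#' Turns percentile knot positions into degrees Celsius for one location.
#'
#' @param spec a [cross_basis_spec()].
#' @param temps the location's observed daily temperatures.
#' @return the spec augmented with `var_knots` and `var_boundary` (degrees C).
#' @export
resolve_basis <- function(spec, temps) {
  temps <- temps[is.finite(temps)]
  if (!length(temps)) stop("no finite temperatures to place knots on", call. = FALSE)
  kn <- as.numeric(quantile(temps, spec$var_percentiles / 100, type = 7))
  spec$var_knots <- kn
  spec$var_boundary <- range(temps)
  if (any(kn <= spec$var_boundary[1]) || any(kn >= spec$var_boundary[2])) {
    stop("degenerate temperature distribution: knots collide with boundary",
         call. = FALSE)
  }
  spec
}

#' Number of exposure-basis columns implied by a resolved spec.
#' @noRd
df_var <- function(spec) length(spec$var_percentiles) + 1L

#' Number of lag-basis columns implied by a spec.
#' @noRd
df_lag <- function(spec) ncol(lag_basis(spec$max_lag, spec$lag_knots))

#' Build the cross-basis matrix of a distributed lag nonlinear model
#'
#' Column (j, k) at day t holds `sum_l b_j(T[t - l]) * c_k(l)` where `b`
#' is the exposure spline and `c` the lag spline: the tensor cross-basis
#' whose linear combination gives the exposure-lag-response surface.
#' The sum is computed as a one-sided convolution of each exposure-basis
#' column with each lag-basis column.  The first L rows (and any row whose
#' lag window touches a missing temperature) are incomplete and flagged.
#'
#' @param temps numeric vector of daily temperatures (consecutive days).
#' @param spec a resolved [cross_basis_spec()] (see [resolve_basis()]); an
#'   unresolved spec is resolved against `temps`.
#' @return an object of class `cross_basis`: the matrix with attributes
#'   `spec`, `complete` (logical row flags) and `provenance` (column map
#'   to variable-basis and lag-basis indices).
#' @export
build_cross_basis <- function(temps, spec) {
  if (is.null(spec$var_knots)) spec <- resolve_basis(spec, temps)
  L <- spec$max_lag
  n <- length(temps)
  if (n < L + 1L) {
    stop(sprintf("series has %d days but the lag window needs at least %d",
                 n, L + 1L), call. = FALSE)
  }
  B <- ns_basis(temps, spec$var_knots, spec$var_boundary)
  C <- lag_basis(L, spec$lag_knots)
  nv <- ncol(B)
  nl <- ncol(C)
  out <- matrix(NA_real_, n, nv * nl)
  prov <- data.frame(var_index = rep(seq_len(nv), each = nl),
                     lag_index = rep(seq_len(nl), times = nv))
  for (j in seq_len(nv)) {
    for (k in seq_len(nl)) {
      col <- (j - 1L) * nl + k
      out[, col] <- as.numeric(stats::filter(B[, j], C[, k],
                                             method = "convolution", sides = 1))
    }
  }
  colnames(out) <- sprintf("v%d.l%d", prov$var_index, prov$lag_index)
  complete <- !is.na(rowSums(out))
  structure(out, spec = spec, complete = complete, provenance = prov,
            class = c("cross_basis", "matrix"))
}

#' Reduction matrix summing the lag dimension of a cross-basis
#'
#' Maps the cross-basis coefficient block onto the coefficients of the
#' overall cumulative exposure-response curve: theta_j = sum_k gamma_jk *
#' sum_l c_k(l).
#'
#' @param spec a resolved cross-basis spec.
#' @return a `df_var x (df_var * df_lag)` matrix.
#' @export
reduction_matrix <- function(spec) {
  C <- lag_basis(spec$max_lag, spec$lag_knots)
  cs <- colSums(C)
  nv <- df_var(spec)
  nl <- length(cs)
  M <- matrix(0, nv, nv * nl)
  for (j in seq_len(nv)) M[j, (j - 1L) * nl + seq_len(nl)] <- cs
  M
}
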