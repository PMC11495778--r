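#' Write a per-location daily series as delimited text
#'
#' Format: comma-separated, header `date,tmean,deaths`, ISO-8601 dates.
#'
#' @param series a `location_series` or compatible data frame.
#' @param path output file path.
#' @export
write_series <- function(series, path) {
  out <- data.frame(date = format(as.Date(series$date), "%Y-%m-%d"),
                    tmean = series$tmean, deaths = series$deaths)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-location daily series.
#'
#' @param path file written by [write_series()].
#' @param location optional location id to attach.
#' @return a `location_series` data frame.
#' @export
read_series <- function(path, location = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("date", "tmean", "deaths") %in% names(df)))
  df$date <- as.Date(df$date)
  structure(df, location = location %||% sub("[.]csv$", "", basename(path)),
            class = c("location_series", "data.frame"))
}

#' Write the location metadata table.
#'
#' Format: `location,country,region,avg_tmean,range_tmean,gdp,zone`.
#'
#' @param metadata metadata data frame ([make_study()] format).
#' @param path output file path.
#' @export
write_metadata <- function(metadata, path) {
  cols <- c("location", "country", "region", "avg_tmean", "range_tmean",
            "gdp", "zone")
  write.csv(metadata[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read the location metadata table.
#' @param path file written by [write_metadata()].
#' @return a data frame.
#' @export
read_metadata <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' Write scenario temperature series.
#'
#' Format: `model,scenario,member,date,tmean`.
#'
#' @param scen scenario series data frame ([make_scenario_series()]).
#' @param path output file path.
#' @export
write_scenario_series <- function(scen, path) {
  out <- data.frame(model = scen$model, scenario = scen$scenario,
                    member = scen$member,
                    date = format(as.Date(scen$date), "%Y-%m-%d"),
                    tmean = scen$tmean)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read scenario temperature series.
#' @param path file written by [write_scenario_series()].
#' @return a data frame with `date` parsed.
#' @export
read_scenario_series <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$date <- as.Date(df$date)
  df
}

#' Write reduced curves (first-stage or BLUP) as delimited text
#'
#' One row per location: centering value, boundary knots, interior knots,
#' coefficients, and the lower triangle (vech) of the covariance.  The
#' shared spec-level basis descriptor (knot percentiles, lag window, lag
#' knots) travels in a JSON side-car so that the pooling and attribution
#' stages are guaranteed to share identical bases.
#'
#' @param curves named list of `reduced_curve` objects.
#' @param path output CSV path.
#' @param descriptor_path output JSON path for the basis descriptor
#'   (default: `path` with a `.basis.json` suffix).
#' @param spec optional [cross_basis_spec()] stored in the descriptor.
#' @export
write_curves <- function(curves, path,
                         descriptor_path = paste0(path, ".basis.json"),
                         spec = NULL) {
  k <- length(curves[[1]]$coef)
  rows <- lapply(curves, function(cv) {
    v <- cv$vcov[lower.tri(cv$vcov, diag = TRUE)]
    c(list(location = cv$location, center = cv$center,
           boundary_low = cv$var_boundary[1], boundary_high = cv$var_boundary[2]),
      setNames(as.list(cv$var_knots), paste0("knot", seq_along(cv$var_knots))),
      setNames(as.list(cv$coef), paste0("theta", seq_len(k))),
      setNames(as.list(v), paste0("vech", seq_along(v))))
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  desc <- list(df_var = k,
               var_percentiles = curves[[1]]$var_percentiles,
               max_lag = spec$max_lag, lag_knots = spec$lag_knots)
  jsonlite::write_json(desc, descriptor_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read reduced curves written by [write_curves()].
#'
#' @param path CSV path.
#' @param descriptor_path JSON basis descriptor path.
#' @return named list of `reduced_curve` objects.
#' @export
read_curves <- function(path, descriptor_path = paste0(path, ".basis.json")) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  desc <- jsonlite::read_json(descriptor_path, simplifyVector = TRUE)
  k <- desc$df_var
  nk <- sum(grepl("^knot", names(df)))
  out <- lapply(seq_len(nrow(df)), function(i) {
    v <- matrix(0, k, k)
    v[lower.tri(v, diag = TRUE)] <- as.numeric(df[i, grepl("^vech", names(df))])
    v <- v + t(v) - diag(diag(v))
    reduced_curve(coef = as.numeric(df[i, paste0("theta", seq_len(k))]),
                  vcov = v,
                  var_knots = as.numeric(df[i, paste0("knot", seq_len(nk))]),
                  var_boundary = c(df$boundary_low[i], df$boundary_high[i]),
                  center = df$center[i], location = df$location[i],
                  var_percentiles = desc$var_percentiles)
  })
  names(out) <- df$location
  out
}

#' Validate a daily series file
#'
#' Checks: parseable ISO-8601 dates, no duplicated dates, non-negative
#' integer death counts, temperatures within physical bounds, and a
#' summary of calendar gaps.
#'
#' @param path file to check.
#' @param temp_bounds admissible temperature range (degrees C).
#' @return an object of class `series_report`: data frame `violations`
#'   (`rule`, `detail`) and `gaps` (count of missing calendar days);
#'   `ok` is `TRUE` when no violation was found.
#' @export
validate_series <- function(path, temp_bounds = c(-60, 60)) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  viol <- list()
  flag <- function(rule, detail) {
    viol[[length(viol) + 1L]] <<- data.frame(rule = rule, detail = detail)
  }
  if (!all(c("date", "tmean", "deaths") %in% names(df))) {
    flag("header", paste("expected date,tmean,deaths; found",
                         paste(names(df), collapse = ",")))
    return(structure(list(violations = do.call(rbind, viol), gaps = NA, ok = FALSE),
                     class = "series_report"))
  }
  d <- as.Date(df$date, format = "%Y-%m-%d")
  bad_dates <- which(is.na(d) & !is.na(df$date))
  if (length(bad_dates)) {
    flag("date_format", sprintf("non-ISO dates at rows %s",
                                paste(head(bad_dates, 5L), collapse = ", ")))
  }
  dup <- unique(df$date[duplicated(df$date)])
  if (length(dup)) {
    flag("duplicate_date", sprintf("duplicated dates: %s",
                                   paste(head(dup, 5L), collapse = ", ")))
  }
  if (any(df$deaths < 0, na.rm = TRUE)) {
    flag("negative_deaths", sprintf("%d rows with deaths < 0",
                                    sum(df$deaths < 0, na.rm = TRUE)))
  }
  if (any(df$deaths %% 1 != 0, na.rm = TRUE)) {
    flag("non_integer_deaths", sprintf("%d rows with non-integer deaths",
                                       sum(df$deaths %% 1 != 0, na.rm = TRUE)))
  }
  out_of_bounds <- df$tmean < temp_bounds[1] | df$tmean > temp_bounds[2]
  if (any(out_of_bounds, na.rm = TRUE)) {
    flag("temperature_bounds", sprintf("%d rows outside [%g, %g] degrees C",
                                       sum(out_of_bounds, na.rm = TRUE),
                                       temp_bounds[1], temp_bounds[2]))
  }
  gaps <- if (all(!is.na(d)) && length(d)) {
    length(seq(min(d), max(d), by = "day")) - length(unique(d))
  } else NA_integer_
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(rule = character(0), detail = character(0))
  structure(list(violations = violations, gaps = gaps,
                 ok = nrow(violations) == 0L),
            class = "series_report")
}
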