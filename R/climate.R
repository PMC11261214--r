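#' Climate parameter set for a location
#'
#' Bundles the three parameters of the smoothed daily temperature model --
#' annual mean `t_mean` (\eqn{\bar T}, degrees C, defined for the reference
#' year 2000), seasonality `seasonality` (\eqn{s}, half the peak-to-trough
#' amplitude of the annual cycle, degrees C) and warming trend `trend`
#' (\eqn{k}, degrees C per 100 years) -- together with location metadata.
#' The calendar is a fixed 365-day year with day 1 = Jan 1, 2000; leap days
#' are ignored.
#'
#' @param t_mean Annual mean temperature in year 2000 (degrees C).
#' @param seasonality Half the annual peak-to-trough temperature range
#'   (degrees C); must be non-negative.
#' @param trend Warming trend (degrees C per 100 years).
#' @param latitude Latitude in degrees North, in \[-90, 90\].
#' @param longitude Longitude in degrees West (metadata only).
#' @param label Short identifier for the location.
#' @return An object of class `climate_params` (a named list).
#' @examples
#' cl <- climate_params(5.103, 19.705, 8.290, latitude = 44, label = "NO")
#' generate_temperature(cl, 1:10)
#' @export
climate_params <- function(t_mean, seasonality, trend, latitude = 40,
                           longitude = NA_real_, label = "custom") {
  stopifnot(is.numeric(t_mean), is.numeric(seasonality), is.numeric(trend))
  if (seasonality < 0) stop("`seasonality` must be >= 0")
  if (latitude < -90 || latitude > 90) stop("`latitude` must be in [-90, 90]")
  structure(
    list(t_mean = as.numeric(t_mean), seasonality = as.numeric(seasonality),
         trend = as.numeric(trend), latitude = as.numeric(latitude),
         longitude = as.numeric(longitude), label = as.character(label)),
    class = "climate_params"
  )
}

#' @export
print.climate_params <- function(x, ...) {
  cat(sprintf(
    "<climate_params> %s (%.1f N): t_mean = %.3f C, seasonality = %.3f C, trend = %.3f C / 100 yr\n",
    x$label, x$latitude, x$t_mean, x$seasonality, x$trend))
  invisible(x)
}

#' Nine reference locations east of the Rocky Mountains
#'
#' Climate parameters for nine agricultural locations in the United States
#' (32-44 degrees N, 84-104 degrees W), derived from smoothed CNRM-CM6-1
#' SSP5-8.5 daily temperature projections. `zstar_a_ref` and `zstar_l_ref`
#' are the published locally adapted thermal optima for aphid and ladybird
#' in 2000, retained as reference metadata; the package computes its own
#' locally adapted optima under its default vital-rate parameters with
#' [find_local_optima()].
#'
#' @return A tibble with one row per location: `id`, `latitude`,
#'   `longitude`, `location`, `t_mean`, `seasonality`, `trend`,
#'   `zstar_a_ref`, `zstar_l_ref`.
#' @examples
#' climate_locations()
#' @export
climate_locations <- function() {
  tibble::tribble(
    ~id,  ~latitude, ~longitude, ~location,                        ~t_mean, ~seasonality, ~trend, ~zstar_a_ref, ~zstar_l_ref,
    "SW", 32,        104,        "Angeles, Texas",                  13.318,  12.398,       7.814,  22.5,         22.0,
    "SO", 32,        94,         "Logansport, Louisiana",           16.889,  10.904,       5.779,  24.5,         24.5,
    "SE", 32,        84,         "Cobb, Georgia",                   15.973,  9.942,        5.793,  22.5,         22.5,
    "CW", 38,        104,        "Fowler, Colorado",                5.055,   13.699,       8.109,  16.0,         15.5,
    "CO", 38,        94,         "Taberville, Missouri",            11.252,  15.805,       7.138,  24.0,         23.5,
    "CE", 38,        84,         "Mt. Sterling, Kentucky",          10.723,  13.264,       6.476,  21.0,         20.5,
    "NW", 44,        104,        "West Pennington, South Dakota",   4.153,   16.159,       7.734,  17.0,         16.5,
    "NO", 44,        94,         "Beauford, Minnesota",             5.103,   19.705,       8.290,  19.0,         18.5,
    "NE", 44,        84,         "Standish, Michigan",              6.477,   15.917,       7.579,  19.0,         19.0
  )
}

#' Look up one of the nine reference locations
#'
#' @param id Two-letter location id (e.g. `"NO"`, `"SO"`).
#' @return A `climate_params` object.
#' @examples
#' climate_location("NO")
#' @export
climate_location <- function(id) {
  tab <- climate_locations()
  row <- tab[tab$id == id, ]
  if (nrow(row) != 1) {
    stop("unknown location id '", id, "'; known ids: ",
         paste(tab$id, collapse = ", "))
  }
  climate_params(row$t_mean, row$seasonality, row$trend,
                 latitude = row$latitude, longitude = row$longitude,
                 label = row$id)
}

#' Generate the smoothed daily temperature series
#'
#' Daily mean temperature on day index `t` (day 1 = Jan 1, 2000) is
#' \deqn{T(t) = -s \cos(2\pi t / 365) + \bar T + k t / 36500,}
#' a 365-day seasonal cosine riding on a linear warming trend.
#'
#' @param params A [climate_params()] object.
#' @param days Integer (or numeric) vector of day indices; must be
#'   non-empty.
#' @return A tibble with columns `day` and `temp_c`.
#' @examples
#' no <- climate_location("NO")
#' generate_temperature(no, 1:365)
#' @export
generate_temperature <- function(params, days) {
  stopifnot(inherits(params, "climate_params"))
  if (length(days) == 0) stop("`days` must be non-empty")
  tibble::tibble(
    day = as.numeric(days),
    temp_c = temperature_at(params, as.numeric(days))
  )
}

# bare vector version used in the simulation hot loop
temperature_at <- function(params, t) {
  -params$seasonality * cos(2 * pi * t / 365) + params$t_mean +
    params$trend * t / 36500
}

#' Fit the three-parameter climate model to a daily temperature series
#'
#' Ordinary least squares of temperature on the regressors
#' \eqn{[1, t, \cos(2\pi t/365), \sin(2\pi t/365)]}. The seasonality is the
#' amplitude of the harmonic pair, the trend is the slope rescaled to
#' degrees C per 100 years, and the annual mean is the intercept (the
#' model's year-2000 reference parameter). Round-trips
#' [generate_temperature()] exactly on noiseless input.
#'
#' @param series A data frame with columns `day` and `temp_c` spanning at
#'   least two full years (>= 730 days).
#' @param latitude Latitude in degrees N attached to the result.
#' @param label Label attached to the result.
#' @return A [climate_params()] object.
#' @examples
#' no <- climate_location("NO")
#' fit_climate_params(generate_temperature(no, 1:3650), latitude = 44)
#' @export
fit_climate_params <- function(series, latitude = 40, label = "fitted") {
  stopifnot(is.data.frame(series), all(c("day", "temp_c") %in% names(series)))
  t <- as.numeric(series$day)
  y <- as.numeric(series$temp_c)
  if (any(!is.finite(y))) stop("temperature series contains non-finite values")
  if (diff(range(t)) < 729) {
    stop("series must span at least 2 full years (730 days); got ",
         round(diff(range(t))) + 1, " days")
  }
  X <- cbind(1, t, cos(2 * pi * t / 365), sin(2 * pi * t / 365))
  beta <- stats::lm.fit(X, y)$coefficients
  # the generator convention is -s*cos(.) with s >= 0; the fitted
  # seasonality is the amplitude of the harmonic pair (phase-free, so a
  # series not aligned to the Jan-1 minimum still gets its amplitude)
  s <- sqrt(beta[3]^2 + beta[4]^2)
  if (s < 1e-12) s <- 0
  climate_params(
    t_mean = unname(beta[1]),
    seasonality = unname(s),
    trend = unname(beta[2]) * 36500,
    latitude = latitude, label = label
  )
}

#' Daylength from latitude and day of year
#'
#' Photoperiod in hours computed with the CBM model of Forsythe et
#' al. (1995): solar declination from a two-term revolution-angle
#' approximation, then the daylight half-angle with a horizon coefficient
#' `p` (degrees below/above the horizon defining "daylight"; the default
#' 0.8333 corresponds to standard sunrise/sunset including refraction and
#' the solar disc). Values are clipped to \[0, 24\] at polar extremes.
#'
#' @param latitude Degrees N.
#' @param day Day of year, 1-365 (vectorized).
#' @param p Horizon coefficient in degrees (default 0.8333).
#' @return Daylength in hours, same length as `day`.
#' @examples
#' daylength(44, 172) # near summer solstice
#' daylength(44, 355) # near winter solstice
#' @export
daylength <- function(latitude, day, p = 0.8333) {
  stopifnot(all(day >= 1), all(day <= 365))
  theta <- 0.2163108 + 2 * atan(0.9671396 * tan(0.00860 * (day - 186)))
  phi_sun <- asin(0.39795 * cos(theta))      # solar declination, radians
  lat <- latitude * pi / 180
  x <- (sin(p * pi / 180) + sin(lat) * sin(phi_sun)) /
    (cos(lat) * cos(phi_sun))
  x <- pmin(1, pmax(-1, x))
  24 - (24 / pi) * acos(x)
}

#' Write / read a daily temperature series as CSV
#'
#' Two-column CSV `day,temp_c` with a header, temperatures written with six
#' decimal places so that write followed by read round-trips bit-exactly at
#' that precision.
#'
#' @param series Tibble with columns `day`, `temp_c`.
#' @param path File path.
#' @return `write_temperature_csv()` returns `path` invisibly;
#'   `read_temperature_csv()` returns a tibble with columns `day`,
#'   `temp_c`.
#' @export
write_temperature_csv <- function(series, path) {
  stopifnot(all(c("day", "temp_c") %in% names(series)))
  lines <- c("day,temp_c",
             sprintf("%d,%.6f", as.integer(series$day), series$temp_c))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_temperature_csv
#' @export
read_temperature_csv <- function(path) {
  dat <- utils::read.csv(path, colClasses = c("integer", "numeric"))
  if (!identical(names(dat), c("day", "temp_c"))) {
    stop("expected CSV header 'day,temp_c'")
  }
  tibble::as_tibble(dat)
}
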