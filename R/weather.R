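#' Construct a season weather table
#'
#' A `season_weather` object is a data frame with one row per calendar day and
#' columns `date`, `t_min`, `t_max`, plus the derived `t_mean = (t_min +
#' t_max)/2` and diurnal range `t_range = t_max - t_min`. Dates must be
#' strictly increasing with no gaps and `t_min <= t_max` on every row.
#'
#' @param date `Date` vector, strictly increasing, daily steps.
#' @param t_min,t_max Daily minimum and maximum air temperature (degrees C).
#' @param site_label Optional site name, stored as an attribute.
#' @return A data frame of class `season_weather`.
#' @export
season_weather <- function(date, t_min, t_max, site_label = "unnamed") {
  date <- as.Date(date)
  if (length(date) == 0L) stop("no records")
  if (length(date) != length(t_min) || length(date) != length(t_max))
    stop("date, t_min and t_max must have equal length")
  d <- as.integer(diff(date))
  if (length(d) && any(d != 1L)) {
    i <- which(d != 1L)[1L]
    stop(sprintf("dates must increase in daily steps: gap or disorder after row %d (%s)",
                 i, format(date[i])))
  }
  bad <- which(t_min > t_max)
  if (length(bad))
    stop(sprintf("t_min > t_max on row %d (%s)", bad[1L], format(date[bad[1L]])))
  w <- data.frame(
    date = date,
    t_min = as.numeric(t_min),
    t_max = as.numeric(t_max),
    t_mean = (as.numeric(t_min) + as.numeric(t_max)) / 2,
    t_range = as.numeric(t_max) - as.numeric(t_min)
  )
  attr(w, "site_label") <- site_label
  class(w) <- c("season_weather", "data.frame")
  w
}

#' Read a daily weather series from a CSV file
#'
#' Expects a header `date,t_min,t_max` with ISO-8601 dates and temperatures in
#' degrees C. Malformed rows (unparseable dates, `t_min > t_max`, gaps,
#' duplicates) are reported with their row number.
#'
#' @param path Path to the CSV file.
#' @param site_label Site name attached to the result (defaults to file name).
#' @return A [season_weather] data frame.
#' @export
read_weather <- function(path, site_label = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("no records in ", path)
  need <- c("date", "t_min", "t_max")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  dates <- as.Date(raw$date)
  if (anyNA(dates))
    stop(sprintf("unparseable date on row %d: '%s'", which(is.na(dates))[1L],
                 raw$date[which(is.na(dates))[1L]]))
  season_weather(dates, raw$t_min, raw$t_max,
                 site_label = site_label %||% basename(path))
}

#' Write a weather series to CSV
#'
#' @param weather A [season_weather] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_weather <- function(weather, path) {
  utils::write.csv(weather[, c("date", "t_min", "t_max")], path, row.names = FALSE)
  invisible(path)
}

#' Synthetic weather specification
#'
#' Parameters of a seasonal-sinusoid temperature generator: daily mean
#' temperature follows `annual_mean + amplitude * sin(...)` peaking on
#' `peak_doy` (default late July), minimum and maximum are the mean minus/plus
#' half the diurnal range plus independent Gaussian day-to-day noise.
#'
#' @param annual_mean Annual mean temperature (degrees C).
#' @param amplitude Seasonal semi-amplitude (degrees C), >= 0.
#' @param diurnal_range Mean daily max-min spread (degrees C), >= 0.
#' @param noise_sd Day-to-day Gaussian noise s.d. (degrees C), >= 0.
#' @param peak_doy Day of year of the seasonal temperature peak.
#' @param n_years Number of consecutive years to generate.
#' @param start_year First calendar year.
#' @param site_label Site name for the generated series.
#' @return A list of class `synthetic_weather_spec`.
#' @export
synthetic_weather_spec <- function(annual_mean = 14.1, amplitude = 15.6,
                                   diurnal_range = 10.5, noise_sd = 1.5,
                                   peak_doy = 208L, n_years = 1L,
                                   start_year = 2007L, site_label = "synthetic") {
  stopifnot(amplitude >= 0, diurnal_range >= 0, noise_sd >= 0)
  if (n_years < 1L) stop("n_years must be positive")
  structure(list(annual_mean = annual_mean, amplitude = amplitude,
                 diurnal_range = diurnal_range, noise_sd = noise_sd,
                 peak_doy = as.integer(peak_doy), n_years = as.integer(n_years),
                 start_year = as.integer(start_year), site_label = site_label),
            class = "synthetic_weather_spec")
}

#' Site climatology presets for the synthetic generator
#'
#' Sinusoid parameters tuned (with zero noise) so that the April-October
#' active accumulated temperature above 12 degrees C matches the published
#' site values: Anyang 4561, Huimin 4518, Aksu 4335 and Yueyang 5245
#' degree-days. Aksu, a continental north-western site, gets a larger diurnal
#' range.
#'
#' @param site One of `"anyang"`, `"huimin"`, `"aksu"`, `"yueyang"`.
#' @param ... Overrides passed on to [synthetic_weather_spec()].
#' @return A `synthetic_weather_spec`.
#' @export
site_weather_spec <- function(site = c("anyang", "huimin", "aksu", "yueyang"), ...) {
  site <- match.arg(site)
  p <- switch(site,
    anyang  = list(annual_mean = 14.1, amplitude = 15.6, diurnal_range = 10.5),
    huimin  = list(annual_mean = 13.5, amplitude = 16.5, diurnal_range = 10.0),
    aksu    = list(annual_mean = 12.0, amplitude = 18.4, diurnal_range = 14.0),
    yueyang = list(annual_mean = 17.0, amplitude = 15.3, diurnal_range = 8.0)
  )
  do.call(synthetic_weather_spec,
          utils::modifyList(c(p, list(site_label = site)), list(...)))
}

#' Generate a synthetic daily weather series
#'
#' Deterministic given `seed`: the same seed always yields the identical
#' series. With zero amplitude and zero noise every day has
#' `t_min = annual_mean - diurnal_range/2` and
#' `t_max = annual_mean + diurnal_range/2`.
#'
#' @param spec A [synthetic_weather_spec].
#' @param seed Integer seed for the day-to-day noise.
#' @return A [season_weather] covering `n_years` full calendar years.
#' @export
generate_weather <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_weather_spec"))
  dates <- seq(as.Date(sprintf("%d-01-01", spec$start_year)),
               as.Date(sprintf("%d-12-31", spec$start_year + spec$n_years - 1L)),
               by = "day")
  doy <- as.integer(strftime(dates, "%j"))
  phase <- spec$peak_doy - 365 / 4
  t_mean <- spec$annual_mean + spec$amplitude * sin(2 * pi * (doy - phase) / 365)
  n <- length(dates)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  e_min <- stats::rnorm(n, 0, spec$noise_sd)
  e_max <- stats::rnorm(n, 0, spec$noise_sd)
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv())
  t_min <- t_mean - spec$diurnal_range / 2 + e_min
  t_max <- t_mean + spec$diurnal_range / 2 + e_max
  # noise must not invert the min/max ordering
  lo <- pmin(t_min, t_max)
  hi <- pmax(t_min, t_max)
  season_weather(dates, lo, hi, site_label = spec$site_label)
}

#' Active accumulated temperature above a base
#'
#' Sum of daily mean temperatures over days whose mean is at or above
#' `t_base`, within a date window. This is the "above 12 degrees C temperature
#' sum" used to characterise Chinese cotton sites.
#'
#' @param weather A [season_weather].
#' @param t_base Base temperature (degrees C), default 12.
#' @param from,to Window bounds (month-day within each year), defaults April 1
#'   and October 31.
#' @return Degree-days (numeric); summed over all years present.
#' @export
thermal_sum <- function(weather, t_base = 12, from = "04-01", to = "10-31") {
  md <- strftime(weather$date, "%m-%d")
  in_win <- md >= from & md <= to
  tm <- weather$t_mean[in_win]
  sum(tm[tm >= t_base])
}

#' Apply the film-mulch temperature increment
#'
#' Plastic film mulching raises early-season temperature; it is modelled as a
#' constant additive increment to both `t_min` and `t_max` (hence `t_mean`)
#' from `start` through `end` inclusive, leaving later days unchanged.
#'
#' @param weather A [season_weather].
#' @param mulch_delta Additive increment (degrees C), >= 0. Default 2.
#' @param start First mulched day (usually the sowing date).
#' @param end Last mulched day; default 60 calendar days after `start`.
#' @return A [season_weather] with adjusted temperatures.
#' @export
apply_film_mulch <- function(weather, mulch_delta = 2, start, end = NULL) {
  stopifnot(inherits(weather, "season_weather"), mulch_delta >= 0)
  start <- as.Date(start)
  end <- if (is.null(end)) start + 60L else as.Date(end)
  if (end < start) stop("mulch end precedes its start")
  sel <- weather$date >= start & weather$date <= end
  season_weather(weather$date,
                 weather$t_min + mulch_delta * sel,
                 weather$t_max + mulch_delta * sel,
                 site_label = attr(weather, "site_label"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
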