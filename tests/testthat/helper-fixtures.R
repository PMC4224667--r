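# shared fixtures: tiny weather series and managements built in code

const_weather <- function(t_min, t_max, from = "2007-04-01", to = "2007-10-31",
                          site = "const") {
  dates <- seq(as.Date(from), as.Date(to), by = "day")
  season_weather(dates, rep(t_min, length(dates)), rep(t_max, length(dates)),
                 site_label = site)
}

# warm season with a cold autumn: optimal temperatures through August, then a
# steep linear decline to well below the base temperature by late October
cold_autumn_weather <- function(year = 2007) {
  dates <- seq(as.Date(sprintf("%d-04-01", year)),
               as.Date(sprintf("%d-10-31", year)), by = "day")
  cut <- as.Date(sprintf("%d-09-01", year))
  tm <- ifelse(dates < cut, 27, 27 - 0.35 * as.numeric(dates - cut))
  season_weather(dates, tm - 5, tm + 5, site_label = "cold-autumn")
}

std_mgmt <- function(year = 2007, ...) {
  management_params(sowing_date = sprintf("%d-04-25", year),
                    main_topping_date = sprintf("%d-07-30", year),
                    branch_topping_date = sprintf("%d-08-15", year),
                    density = 6, ...)
}

no_abscission_params <- function(...) {
  model_params(arch = arch_params(
    abscission = data.frame(age_from = 0, age_to = Inf, daily_p = 0), ...))
}
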