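#' Cardinal temperatures for physiological time
#'
#' Development is clocked in physiological days: one physiological day is one
#' calendar day at or above the optimal temperature. The default base and
#' optimal temperatures for cotton boll development are 12 and 25 degrees C.
#'
#' @param t_base Base temperature (degrees C), below which no development.
#' @param t_opt Optimal temperature (degrees C), at or above which one full
#'   physiological day accrues per calendar day.
#' @return A list of class `thermal_params`.
#' @export
thermal_params <- function(t_base = 12, t_opt = 25) {
  if (!(t_base < t_opt)) stop("t_base must be below t_opt")
  structure(list(t_base = t_base, t_opt = t_opt), class = "thermal_params")
}

#' Daily temperature effect on development
#'
#' The fraction of a physiological day accrued on a calendar day with mean
#' temperature `t_mean`: `(t_mean - t_base) / (t_opt - t_base)`, clamped to
#' zero below the base temperature and to one above the optimum. Piecewise
#' linear, continuous and non-decreasing in `t_mean`; vectorised.
#'
#' @param t_mean Daily mean temperature(s), degrees C.
#' @param params A [thermal_params] list.
#' @return Fraction(s) in `[0, 1]`.
#' @export
daily_temperature_effect <- function(t_mean, params = thermal_params()) {
  pmin(1, pmax(0, (t_mean - params$t_base) / (params$t_opt - params$t_base)))
}

#' Accumulate physiological days over a weather series
#'
#' @param weather A [season_weather].
#' @param params A [thermal_params] list.
#' @return Numeric vector of cumulative physiological days, one per row of
#'   `weather` (value at the end of each day).
#' @export
physiological_age <- function(weather, params = thermal_params()) {
  cumsum(daily_temperature_effect(weather$t_mean, params))
}

#' Advance a physiological clock by one day's effect
#'
#' @param clock Accumulated physiological days (numeric scalar >= 0).
#' @param effect A daily effect in `[0, 1]` from
#'   [daily_temperature_effect()].
#' @return Updated clock.
#' @export
accumulate <- function(clock, effect) {
  if (any(effect < 0)) stop("negative daily effect")
  clock + sum(effect)
}
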