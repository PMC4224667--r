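#' Fibre-quality parameter set
#'
#' Logistic potential-quality constants and temperature reduction-factor
#' coefficients for the three fibre quality indices: length (mm), strength
#' (cN/tex) and micronaire (unitless). The potential value of index i at fruit
#' age t (physiological days after squaring) is
#' `q_max / (1 + exp(-k * (t - t_m)))`; its daily increment is reduced by
#' temperature factors specific to each index: length responds to daily mean
#' temperature only (quadratic, optimum near 25 degrees C), strength to daily
#' mean (increasing linear, saturating above 30 degrees C) and to the diurnal
#' range (decreasing linear), micronaire to the daily minimum (increasing
#' linear, saturating above 25 degrees C).
#'
#' Defaults are the calibrated values for a standard cultivar; both tested
#' cultivars behaved identically, so a single set is used.
#'
#' @param q_max Named vector of asymptotic values per index.
#' @param k Named vector of relative growth rates (per physiological day).
#' @param t_m Named vector of inflection ages (physiological days).
#' @param length_mean_coef Quadratic coefficients (a, b, c) of the
#'   length-vs-mean-temperature factor `a*T^2 + b*T + c`.
#' @param strength_mean_coef Linear coefficients (slope, intercept) of the
#'   strength-vs-mean-temperature factor.
#' @param strength_td_coef Linear coefficients (slope, intercept) of the
#'   strength-vs-diurnal-range factor.
#' @param micronaire_tmin_coef Linear coefficients (slope, intercept) of the
#'   micronaire-vs-minimum-temperature factor.
#' @return A list of class `quality_params`.
#' @export
quality_params <- function(
    q_max = c(length = 30.47, strength = 30.94, micronaire = 4.648),
    k     = c(length = 0.28,  strength = 0.23,  micronaire = 0.22),
    t_m   = c(length = 33.78, strength = 39.97, micronaire = 47.03),
    length_mean_coef     = c(a = -0.0038, b = 0.1904, c = -1.3694),
    strength_mean_coef   = c(slope = 0.0198, intercept = 0.4657),
    strength_td_coef     = c(slope = -0.0216, intercept = 1.136),
    micronaire_tmin_coef = c(slope = 0.0244, intercept = 0.3874)) {
  idx <- c("length", "strength", "micronaire")
  stopifnot(all(idx %in% names(q_max)), all(idx %in% names(k)),
            all(idx %in% names(t_m)),
            all(q_max[idx] > 0), all(k[idx] > 0), all(t_m[idx] > 0))
  structure(list(q_max = q_max[idx], k = k[idx], t_m = t_m[idx],
                 length_mean_coef = length_mean_coef,
                 strength_mean_coef = strength_mean_coef,
                 strength_td_coef = strength_td_coef,
                 micronaire_tmin_coef = micronaire_tmin_coef),
            class = "quality_params")
}

#' Potential fibre quality at a given fruit age
#'
#' Logistic curve of potential quality under optimal temperature,
#' `q_max / (1 + exp(-k (t - t_m)))`, evaluated at physiological age `age`.
#'
#' @param age Fruit age, physiological days since squaring (>= 0); vectorised.
#' @param index `"length"`, `"strength"` or `"micronaire"`.
#' @param params A [quality_params] list.
#' @return Potential value(s) in the index's units.
#' @export
potential_quality <- function(age, index = c("length", "strength", "micronaire"),
                              params = quality_params()) {
  index <- match.arg(index)
  if (any(age < 0)) stop("age must be non-negative")
  params$q_max[[index]] /
    (1 + exp(-params$k[[index]] * (age - params$t_m[[index]])))
}

#' Fruit age of maximal potential growth rate
#'
#' Numerically maximises the first derivative of the potential-quality
#' logistic over fruit age. For a logistic this is its inflection point; the
#' value is located by golden-section search rather than read off the
#' parameters, so it doubles as a consistency check.
#'
#' @inheritParams potential_quality
#' @param upper Upper bound of the search interval (physiological days).
#' @return Age (physiological days) of the maximal growth rate.
#' @export
peak_growth_age <- function(index = c("length", "strength", "micronaire"),
                            params = quality_params(), upper = 120) {
  index <- match.arg(index)
  rate <- function(t) {
    h <- 1e-4
    (potential_quality(t + h, index, params) -
       potential_quality(pmax(t - h, 0), index, params)) / (2 * h)
  }
  stats::optimize(rate, c(0, upper), maximum = TRUE)$maximum
}

clamp01 <- function(x) pmin(1, pmax(0, x))

#' Mean-temperature reduction factor for fibre length
#'
#' Quadratic in the daily mean temperature with its maximum near 25 degrees C
#' and falling to zero near the 9 and 42 degree C thresholds for fibre growth;
#' output clamped to `[0, 1]` (the raw vertex slightly exceeds 1).
#'
#' @param t_mean Daily mean temperature, degrees C; vectorised.
#' @param params A [quality_params] list.
#' @param clamp If `FALSE`, return the raw polynomial value (diagnostics).
#' @return Fraction(s) in `[0, 1]` (when clamped).
#' @export
length_mean_temp_factor <- function(t_mean, params = quality_params(),
                                    clamp = TRUE) {
  cf <- params$length_mean_coef
  raw <- cf[["a"]] * t_mean^2 + cf[["b"]] * t_mean + cf[["c"]]
  if (clamp) clamp01(raw) else raw
}

#' Mean-temperature reduction factor for fibre strength
#'
#' Increasing linear function of daily mean temperature, equal to 1 for means
#' above 30 degrees C (via the upper clamp).
#'
#' @inheritParams length_mean_temp_factor
#' @return Fraction(s) in `[0, 1]` (when clamped).
#' @export
strength_mean_temp_factor <- function(t_mean, params = quality_params(),
                                      clamp = TRUE) {
  cf <- params$strength_mean_coef
  raw <- cf[["slope"]] * t_mean + cf[["intercept"]]
  if (clamp) clamp01(raw) else raw
}

#' Diurnal-range reduction factor for fibre strength
#'
#' Decreasing linear function of the daily max-min temperature difference.
#'
#' @param t_range Daily diurnal range (degrees C), >= 0; vectorised.
#' @inheritParams length_mean_temp_factor
#' @return Fraction(s) in `[0, 1]` (when clamped).
#' @export
strength_td_factor <- function(t_range, params = quality_params(),
                               clamp = TRUE) {
  if (any(t_range < 0)) stop("t_range must be non-negative")
  cf <- params$strength_td_coef
  raw <- cf[["slope"]] * t_range + cf[["intercept"]]
  if (clamp) clamp01(raw) else raw
}

#' Minimum-temperature reduction factor for micronaire
#'
#' Increasing linear function of the daily minimum temperature, equal to 1 for
#' minima above 25 degrees C (via the upper clamp).
#'
#' @param t_min Daily minimum temperature, degrees C; vectorised.
#' @inheritParams length_mean_temp_factor
#' @return Fraction(s) in `[0, 1]` (when clamped).
#' @export
micronaire_tmin_factor <- function(t_min, params = quality_params(),
                                   clamp = TRUE) {
  cf <- params$micronaire_tmin_coef
  raw <- cf[["slope"]] * t_min + cf[["intercept"]]
  if (clamp) clamp01(raw) else raw
}

#' Combined reduction factor for one index on one day
#'
#' Length responds to the daily mean only; strength to the daily mean and the
#' diurnal range (product); micronaire to the daily minimum only.
#'
#' @param index `"length"`, `"strength"` or `"micronaire"`.
#' @param t_mean,t_min,t_range Day's temperatures, degrees C.
#' @param params A [quality_params] list.
#' @return Fraction in `[0, 1]`.
#' @export
reduction_factor <- function(index, t_mean, t_min, t_range,
                             params = quality_params()) {
  switch(index,
    length = length_mean_temp_factor(t_mean, params),
    strength = strength_mean_temp_factor(t_mean, params) *
      strength_td_factor(t_range, params),
    micronaire = micronaire_tmin_factor(t_min, params),
    stop("unknown index: ", index))
}

#' Actual daily increment of a fibre-quality index
#'
#' The potential increment is the difference of the potential logistic between
#' the fruit's age after and before the day (both on the physiological-day
#' clock, so a cold day both slows ageing and, through the factors, shrinks
#' what little increment remains). The actual increment multiplies it by the
#' day's reduction factor for the index.
#'
#' @param age_before,age_after Fruit age (physiological days) at the start and
#'   end of the day; `age_after >= age_before`.
#' @param index Quality index name.
#' @param t_mean,t_min,t_range Day's temperatures, degrees C.
#' @param params A [quality_params] list.
#' @return Non-negative increment, at most the potential increment.
#' @export
daily_quality_increment <- function(age_before, age_after, index,
                                    t_mean, t_min, t_range,
                                    params = quality_params()) {
  stopifnot(age_after >= age_before)
  d_pot <- potential_quality(age_after, index, params) -
    potential_quality(age_before, index, params)
  d_pot * reduction_factor(index, t_mean, t_min, t_range, params)
}
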