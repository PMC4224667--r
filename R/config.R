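#' Load a simulation configuration from YAML
#'
#' Recognised top-level keys, all optional and merged over package defaults:
#' `thermal` (t_base, t_opt), `quality` (q_max/k/t_m per index plus
#' reduction-factor coefficient vectors), `arch` (architectural and
#' phenological keys of [arch_params()], including an `abscission` table),
#' `management` (sowing_date, topping dates, density, mc_applied,
#' film_mulch) and `weather` (a [synthetic_weather_spec()] block).
#'
#' @param path YAML file path.
#' @return List with `params` (a [model_params]), `mgmt` (a
#'   [management_params] or `NULL`) and `weather_spec` (a
#'   `synthetic_weather_spec` or `NULL`).
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  th <- do.call(thermal_params, cfg$thermal %||% list())
  qa <- cfg$quality %||% list()
  for (nm in c("q_max", "k", "t_m", "length_mean_coef", "strength_mean_coef",
               "strength_td_coef", "micronaire_tmin_coef"))
    if (!is.null(qa[[nm]])) qa[[nm]] <- unlist(qa[[nm]])
  qd <- quality_params()
  for (nm in c("q_max", "k", "t_m"))
    if (!is.null(qa[[nm]])) {
      v <- qd[[nm]]; v[names(qa[[nm]])] <- qa[[nm]]; qa[[nm]] <- v
    }
  qu <- do.call(quality_params, qa)
  ar <- cfg$arch %||% list()
  if (!is.null(ar$abscission)) ar$abscission <- as.data.frame(ar$abscission)
  for (nm in c("plastochron_range", "density_range"))
    if (!is.null(ar[[nm]])) ar[[nm]] <- unlist(ar[[nm]])
  arch <- do.call(arch_params, ar)
  mgmt <- if (!is.null(cfg$management))
    do.call(management_params, cfg$management) else NULL
  wsp <- if (!is.null(cfg$weather))
    do.call(synthetic_weather_spec, cfg$weather) else NULL
  list(params = model_params(thermal = th, quality = qu, arch = arch),
       mgmt = mgmt, weather_spec = wsp)
}

#' Write a quality parameter set as a YAML block
#'
#' Serialises the logistic constants and reduction-factor coefficients under
#' a top-level `quality` key, in the shape [load_config()] reads back.
#'
#' @param params A [quality_params] list.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_quality_params <- function(params, path) {
  block <- list(quality = list(
    q_max = as.list(params$q_max), k = as.list(params$k),
    t_m = as.list(params$t_m),
    length_mean_coef = as.list(params$length_mean_coef),
    strength_mean_coef = as.list(params$strength_mean_coef),
    strength_td_coef = as.list(params$strength_td_coef),
    micronaire_tmin_coef = as.list(params$micronaire_tmin_coef)))
  yaml::write_yaml(block, path)
  invisible(path)
}
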