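#' Regional farmer-practice presets
#'
#' Standard management anchors by cotton region: sowing, main-stem topping
#' and branch topping dates, plant density and film-mulch use. Xinjiang sows
#' April 10, tops the main stem July 20 and branches August 5 at 18 plants/m2
#' under film mulch; the Yellow River region uses April 25 / July 30 /
#' August 15 at 6 plants/m2; the Yangtze River region April 10 / August 10 /
#' August 25 at 6 plants/m2; neither of the latter mulches. Each region is
#' paired with a representative synthetic-weather site.
#'
#' @param region `"xinjiang"`, `"yellow_river"` or `"yangtze"`.
#' @return List with `sowing`, `main_topping`, `branch_topping` (month-day
#'   strings), `density`, `mulch`, `site`.
#' @export
region_preset <- function(region = c("xinjiang", "yellow_river", "yangtze")) {
  region <- match.arg(region)
  switch(region,
    xinjiang = list(sowing = "04-10", main_topping = "07-20",
                    branch_topping = "08-05", density = 18, mulch = TRUE,
                    site = "aksu"),
    yellow_river = list(sowing = "04-25", main_topping = "07-30",
                        branch_topping = "08-15", density = 6, mulch = FALSE,
                        site = "huimin"),
    yangtze = list(sowing = "04-10", main_topping = "08-10",
                   branch_topping = "08-25", density = 6, mulch = FALSE,
                   site = "yueyang"))
}

#' Scenario specification
#'
#' A region preset plus day offsets applied to its farmer-practice dates, the
#' standard menu being sowing offsets {-20,-10,0,+10,+20,+30}, main-stem
#' topping offsets {-10,-5,0,+5,+10,+15} and branch topping offsets
#' {0,+10,+20,+30}, with or without film mulch.
#'
#' @param region Region name, see [region_preset()].
#' @param sowing_offset,main_topping_offset,branch_topping_offset Day offsets
#'   relative to farmer practice.
#' @param mulch Override the region's mulch default (`NULL` keeps it).
#' @param n_plants Plants simulated per year.
#' @param years Calendar years to simulate (integer vector).
#' @param seed Base seed; every weather draw and abscission draw derives
#'   from it.
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(region = "yellow_river", sowing_offset = 0,
                          main_topping_offset = 0, branch_topping_offset = 0,
                          mulch = NULL, n_plants = 6L, years = 2007L,
                          seed = 1L) {
  preset <- region_preset(region)
  if (n_plants < 1L) stop("n_plants must be >= 1")
  structure(list(region = region, preset = preset,
                 sowing_offset = sowing_offset,
                 main_topping_offset = main_topping_offset,
                 branch_topping_offset = branch_topping_offset,
                 mulch = if (is.null(mulch)) preset$mulch else isTRUE(mulch),
                 n_plants = as.integer(n_plants),
                 years = as.integer(years), seed = as.integer(seed)),
            class = "scenario_spec")
}

scenario_mgmt <- function(spec, year) {
  p <- spec$preset
  d <- function(md, off) as.Date(sprintf("%d-%s", year, md)) + off
  management_params(
    sowing_date = d(p$sowing, spec$sowing_offset),
    main_topping_date = d(p$main_topping, spec$main_topping_offset),
    branch_topping_date = d(p$branch_topping, spec$branch_topping_offset),
    density = p$density, film_mulch = spec$mulch)
}

#' Run one management scenario
#'
#' Simulates `n_plants` plants for each requested year and aggregates the
#' per-fruit results: plant-level means and standard deviations of final
#' length, strength and micronaire over retained bolls, the mean-quality
#' profile against cumulative phytomer number, and quality-frequency
#' histograms. Fully deterministic given the spec's seed.
#'
#' @param spec A [scenario_spec].
#' @param weather Either `NULL` (weather generated from the region's site
#'   preset, one series per year), a single [season_weather] covering all
#'   years, or a list of them named by year.
#' @param params A [model_params] list.
#' @return List of class `scenario_result` with elements `spec`, `fruits`
#'   (all initiated fruits, with `year` and `plant_id`), `means`,
#'   `cpn_profile`, `histograms`.
#' @export
run_scenario <- function(spec, weather = NULL, params = model_params()) {
  stopifnot(inherits(spec, "scenario_spec"))
  all_fruits <- list()
  for (yi in seq_along(spec$years)) {
    year <- spec$years[yi]
    w <- scenario_weather(spec, weather, year, yi)
    if (!any(strftime(w$date, "%Y") == as.character(year)))
      stop("weather does not cover year ", year)
    mgmt <- scenario_mgmt(spec, year)
    for (p in seq_len(spec$n_plants)) {
      seed_p <- (spec$seed + 7919L * yi + 104729L * p) %% .Machine$integer.max
      plant <- simulate_plant(w, mgmt, params, seed = seed_p)
      ft <- fruit_table(plant, plant_id = p)
      if (nrow(ft)) ft$year <- year
      all_fruits[[length(all_fruits) + 1L]] <- ft
    }
  }
  fruits <- do.call(rbind, all_fruits)
  structure(list(spec = spec, fruits = fruits,
                 means = plant_mean_quality(fruits),
                 cpn_profile = if (any(retained_boll(fruits)))
                   cpn_profile(fruits) else NULL,
                 histograms = if (any(retained_boll(fruits)))
                   lapply(stats::setNames(nm = c("length", "strength",
                                                 "micronaire")),
                          function(i) quality_histogram(fruits, i)) else NULL),
            class = "scenario_result")
}

scenario_weather <- function(spec, weather, year, yi) {
  if (is.null(weather)) {
    sp <- site_weather_spec(spec$preset$site, n_years = 1L, start_year = year)
    return(generate_weather(sp, seed = (spec$seed + 15485863L * yi) %%
                              .Machine$integer.max))
  }
  if (inherits(weather, "season_weather")) return(weather)
  w <- weather[[as.character(year)]]
  if (is.null(w)) stop("no weather supplied for year ", year)
  w
}

retained_boll <- function(fruits) {
  fruits$fate == "alive" & fruits$final_stage %in% c("boll", "open-boll")
}

#' Plant-level mean quality over retained bolls
#'
#' @param fruits A per-fruit table from [fruit_table()] or
#'   `scenario_result$fruits`. Abscised and pruned fruits are excluded, as are
#'   fruits that never set a boll.
#' @return Data frame `index, mean, sd, n`.
#' @export
plant_mean_quality <- function(fruits) {
  keep <- fruits[retained_boll(fruits), , drop = FALSE]
  cols <- c(length = "length_mm", strength = "strength_cN_tex",
            micronaire = "micronaire")
  data.frame(index = names(cols),
             mean = vapply(cols, function(cl) mean(keep[[cl]]), 0),
             sd = vapply(cols, function(cl) stats::sd(keep[[cl]]), 0),
             n = nrow(keep), row.names = NULL)
}

#' Mean fibre quality by cumulative phytomer number
#'
#' Groups retained bolls by CPN and returns the mean of each quality index
#' with twice its standard error, the usual error bar for cohort profiles.
#'
#' @inheritParams plant_mean_quality
#' @return Data frame `cpn, n, length_mean, length_2se, strength_mean,
#'   strength_2se, micronaire_mean, micronaire_2se`, ordered by CPN.
#' @export
cpn_profile <- function(fruits) {
  keep <- fruits[retained_boll(fruits), , drop = FALSE]
  if (nrow(keep) == 0L) stop("no retained bolls to profile")
  cols <- c(length = "length_mm", strength = "strength_cN_tex",
            micronaire = "micronaire")
  out <- data.frame(cpn = sort(unique(keep$cpn)))
  out$n <- vapply(out$cpn, function(cc) sum(keep$cpn == cc), 0L)
  for (nm in names(cols)) {
    v <- cols[[nm]]
    out[[paste0(nm, "_mean")]] <-
      vapply(out$cpn, function(cc) mean(keep[[v]][keep$cpn == cc]), 0)
    se <- vapply(out$cpn, function(cc) {
      x <- keep[[v]][keep$cpn == cc]
      if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0
    }, 0)
    out[[paste0(nm, "_2se")]] <- 2 * se
  }
  out
}

#' Default histogram bin edges per quality index
#'
#' Five-unit bins for length (mm) and strength (cN/tex), 0.75-wide bins for
#' micronaire, matching the conventional reporting classes (e.g. 30-35 mm,
#' 4.5-5.25 micronaire).
#'
#' @param index Quality index name.
#' @return Numeric vector of increasing edges.
#' @export
default_bin_edges <- function(index = c("length", "strength", "micronaire")) {
  index <- match.arg(index)
  switch(index,
    length = seq(0, 45, by = 5),
    strength = seq(0, 45, by = 5),
    micronaire = seq(0, 7.5, by = 0.75))
}

#' Quality-frequency histogram over retained bolls
#'
#' Counts retained bolls per quality bin; values falling outside the supplied
#' edges are collected in open-ended bins at either extreme, so the counts
#' always sum to the number of retained bolls.
#'
#' @inheritParams plant_mean_quality
#' @param index Quality index name.
#' @param edges Increasing bin edges; defaults per [default_bin_edges()].
#' @return Data frame `bin, from, to, count`.
#' @export
quality_histogram <- function(fruits, index = c("length", "strength",
                                                "micronaire"),
                              edges = NULL) {
  index <- match.arg(index)
  if (is.null(edges)) edges <- default_bin_edges(index)
  if (is.unsorted(edges, strictly = TRUE)) stop("bin edges must increase")
  keep <- fruits[retained_boll(fruits), , drop = FALSE]
  col <- c(length = "length_mm", strength = "strength_cN_tex",
           micronaire = "micronaire")[[index]]
  full <- c(-Inf, edges, Inf)
  cts <- if (nrow(keep)) as.vector(table(cut(keep[[col]], full, right = FALSE)))
         else rep(0L, length(full) - 1L)
  data.frame(bin = levels(cut(numeric(), full, right = FALSE)),
             from = full[-length(full)], to = full[-1L], count = cts)
}

#' Run the full management sweep for a region
#'
#' One-factor-at-a-time grid over the standard offset menus: sowing date,
#' main-stem topping, branch topping, and mulch on/off, each varied with all
#' other practices at the farmer's defaults.
#'
#' @param region Region name.
#' @param years,n_plants,seed Passed to each [scenario_spec()].
#' @param weather Optional weather (see [run_scenario()]).
#' @param params A [model_params] list.
#' @return Data frame, one row per scenario cell and index: `treatment`,
#'   `level`, `index`, `mean`, `sd`, `n`.
#' @export
run_sweep <- function(region = "yellow_river", years = 2007L, n_plants = 6L,
                      seed = 1L, weather = NULL, params = model_params()) {
  cells <- rbind(
    data.frame(treatment = "sowing", level = c(-20, -10, 0, 10, 20, 30)),
    data.frame(treatment = "main_topping", level = c(-10, -5, 0, 5, 10, 15)),
    data.frame(treatment = "branch_topping", level = c(0, 10, 20, 30)),
    data.frame(treatment = "mulch", level = c(1, 0)))
  out <- list()
  for (i in seq_len(nrow(cells))) {
    tr <- cells$treatment[i]; lv <- cells$level[i]
    spec <- scenario_spec(
      region,
      sowing_offset = if (tr == "sowing") lv else 0,
      main_topping_offset = if (tr == "main_topping") lv else 0,
      branch_topping_offset = if (tr == "branch_topping") lv else 0,
      mulch = if (tr == "mulch") lv == 1 else NULL,
      n_plants = n_plants, years = years, seed = seed)
    m <- run_scenario(spec, weather, params)$means
    m$treatment <- tr
    m$level <- lv
    out[[i]] <- m[, c("treatment", "level", "index", "mean", "sd", "n")]
  }
  do.call(rbind, out)
}

#' Write a per-fruit table to CSV
#'
#' @param fruits Per-fruit data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fruit_csv <- function(fruits, path) {
  utils::write.csv(fruits, path, row.names = FALSE)
  invisible(path)
}

#' Read a per-fruit table written by [write_fruit_csv()]
#'
#' @param path CSV path.
#' @return Per-fruit data frame with `squaring_date` restored as `Date`.
#' @export
read_fruit_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$squaring_date <- as.Date(x$squaring_date)
  x
}
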