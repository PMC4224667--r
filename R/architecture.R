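#' Architectural and phenological parameters
#'
#' Defaults describe a standard simulated plant: the first fruiting branch at
#' main-stem rank 7, three fruiting nodes per branch, an 8-physiological-day
#' lag from sowing to the first phytomer, squares turning to flowers after 23
#' physiological days and bolls opening 50 physiological days after flowering.
#' The plastochron map and the age-dependent abscission table are
#' non-authoritative placeholders (the calibrated values live in companion
#' process models and are not published here); override them from a config
#' file for serious use.
#'
#' @param emergence_lag Physiological days from sowing to the first phytomer.
#' @param first_fruiting_rank Main-stem rank bearing the first fruiting branch.
#' @param nodes_per_branch Fruiting nodes per branch (before topping).
#' @param dur_square Physiological days from squaring to flowering.
#' @param dur_flower Physiological days a flower persists before the boll sets.
#' @param opening_age Fruit age (physiological days since squaring) at boll
#'   opening; quality accumulation stops here.
#' @param plastochron_range Plastochron endpoints (physiological days) at the
#'   low- and high-density ends of the map.
#' @param density_range Plant densities (plants/m2) mapped to the plastochron
#'   endpoints; log-linear in between.
#' @param mc_delta Plastochron increase when mepiquat chloride is applied
#'   (slower development), capped at the upper plastochron endpoint.
#' @param abscission Data frame `age_from, age_to, daily_p`: daily abscission
#'   probability by fruit age (physiological days), piecewise constant.
#' @param mulch_delta Film-mulch air-temperature increment, degrees C.
#' @param mulch_duration Calendar days after sowing the mulch increment lasts.
#' @return A list of class `arch_params`.
#' @export
arch_params <- function(emergence_lag = 8, first_fruiting_rank = 7L,
                        nodes_per_branch = 3L,
                        dur_square = 23, dur_flower = 3, opening_age = 73,
                        plastochron_range = c(3.0, 3.5),
                        density_range = c(1, 6),
                        mc_delta = 0.25,
                        abscission = default_abscission_table(),
                        mulch_delta = 2, mulch_duration = 60L) {
  stopifnot(dur_square > 0, dur_flower > 0, opening_age > dur_square + dur_flower,
            length(plastochron_range) == 2L, length(density_range) == 2L,
            all(c("age_from", "age_to", "daily_p") %in% names(abscission)))
  structure(list(emergence_lag = emergence_lag,
                 first_fruiting_rank = as.integer(first_fruiting_rank),
                 nodes_per_branch = as.integer(nodes_per_branch),
                 dur_square = dur_square, dur_flower = dur_flower,
                 opening_age = opening_age,
                 plastochron_range = plastochron_range,
                 density_range = density_range, mc_delta = mc_delta,
                 abscission = abscission,
                 mulch_delta = mulch_delta,
                 mulch_duration = as.integer(mulch_duration)),
            class = "arch_params")
}

#' Default age-dependent abscission table (placeholder)
#'
#' Piecewise-constant daily abscission probability versus fruit age in
#' physiological days, with a peak for young bolls. Chosen for a season-end
#' retention of roughly three quarters; it is a placeholder, not a calibrated
#' rate, and should be overridden where retention matters.
#'
#' @return Data frame with columns `age_from`, `age_to`, `daily_p`.
#' @export
default_abscission_table <- function() {
  data.frame(age_from = c(0, 10, 23, 38),
             age_to   = c(10, 23, 38, Inf),
             daily_p  = c(0.002, 0.004, 0.012, 0.001))
}

#' Daily abscission probability at a given fruit age
#'
#' @param age Fruit age(s), physiological days.
#' @param table Abscission table as in [default_abscission_table()].
#' @return Daily probability per fruit.
#' @export
abscission_probability <- function(age, table = default_abscission_table()) {
  i <- findInterval(age, table$age_from)
  i[i < 1L] <- 1L
  table$daily_p[i]
}

#' Full model parameter set
#'
#' @param thermal A [thermal_params] list.
#' @param quality A [quality_params] list.
#' @param arch An [arch_params] list.
#' @return A list of class `model_params`.
#' @export
model_params <- function(thermal = thermal_params(),
                         quality = quality_params(),
                         arch = arch_params()) {
  structure(list(thermal = thermal, quality = quality, arch = arch),
            class = "model_params")
}

#' Management configuration for one plant/season
#'
#' @param sowing_date Sowing date.
#' @param main_topping_date Calendar date of main-stem topping (or `NA`).
#' @param branch_topping_date Calendar date of branch topping (or `NA`).
#' @param density Plant population density, plants/m2.
#' @param mc_applied Whether mepiquat chloride is applied.
#' @param film_mulch Whether plastic film mulch is applied.
#' @return A list of class `management_params`.
#' @export
management_params <- function(sowing_date, main_topping_date = NA,
                              branch_topping_date = NA, density = 6,
                              mc_applied = FALSE, film_mulch = FALSE) {
  sowing_date <- as.Date(sowing_date)
  main_topping_date <- as.Date(main_topping_date)
  branch_topping_date <- as.Date(branch_topping_date)
  if (density <= 0) stop("density must be positive")
  if (!is.na(main_topping_date) && main_topping_date <= sowing_date)
    stop("main-stem topping must follow sowing")
  if (!is.na(main_topping_date) && !is.na(branch_topping_date) &&
      branch_topping_date < main_topping_date)
    stop("branch topping must not precede main-stem topping")
  structure(list(sowing_date = sowing_date,
                 main_topping_date = main_topping_date,
                 branch_topping_date = branch_topping_date,
                 density = density, mc_applied = isTRUE(mc_applied),
                 film_mulch = isTRUE(film_mulch)),
            class = "management_params")
}

#' Plastochron as a function of density and growth-regulator use
#'
#' Phytomer appearance interval in physiological days, within 3.0-3.5.
#' Log-linear in density between the two endpoints of `density_range`;
#' mepiquat chloride slows development by `mc_delta`, capped at the upper
#' endpoint.
#'
#' @param density Plant density, plants/m2 (> 0).
#' @param mc_applied Whether mepiquat chloride is applied.
#' @param arch An [arch_params] list.
#' @return Plastochron, physiological days.
#' @export
plastochron <- function(density, mc_applied = FALSE, arch = arch_params()) {
  if (density <= 0) stop("density must be positive")
  pr <- arch$plastochron_range
  dr <- arch$density_range
  f <- (log(density) - log(dr[1])) / (log(dr[2]) - log(dr[1]))
  p <- pr[1] + (pr[2] - pr[1]) * min(1, max(0, f))
  if (isTRUE(mc_applied)) p <- p + arch$mc_delta
  min(p, pr[2])
}

#' Cumulative phytomer number of a fruit position
#'
#' The CPN counts phytomers from the cotyledon node up the main stem to the
#' phytomer subtending the fruiting branch, then along the branch to the
#' fruit's node: `branch_rank + node_on_branch`. Fruits sharing a CPN appear
#' at the same physiological time and form one age cohort.
#'
#' @param branch_rank Main-stem rank of the subtending phytomer (>= 1).
#' @param node_on_branch Node position along the branch (>= 1).
#' @return Integer CPN.
#' @export
assign_cpn <- function(branch_rank, node_on_branch) {
  if (any(branch_rank < 1L) || any(node_on_branch < 1L))
    stop("unknown position: ranks and nodes start at 1")
  as.integer(branch_rank + node_on_branch)
}

empty_fruit_table <- function() {
  data.frame(branch_rank = integer(), node = integer(), cpn = integer(),
             squaring_clock = numeric(), squaring_date = as.Date(character()),
             age = numeric(), stage = character(), fate = character(),
             length = numeric(), strength = numeric(), micronaire = numeric(),
             stringsAsFactors = FALSE)
}

#' Initialise a plant at sowing
#'
#' @param mgmt A [management_params] list.
#' @param params A [model_params] list.
#' @return A list of class `plant_state`.
#' @export
new_plant <- function(mgmt, params = model_params()) {
  structure(list(
    clock = 0,
    date = mgmt$sowing_date - 1L,
    main_rank = 0L,
    main_apex = TRUE,
    branch_apex = TRUE,
    branch_topped = FALSE,
    branch_nodes = integer(),   # appeared nodes, named by main-stem rank
    branch_cap = integer(),     # max nodes allowed per branch (after topping)
    plastochron = plastochron(mgmt$density, mgmt$mc_applied, params$arch),
    fruits = empty_fruit_table()
  ), class = "plant_state")
}

#' Developmental stage of a fruit at a given age
#'
#' Stages progress square -> flower -> boll -> open-boll at the configured
#' physiological-day thresholds; open-boll is absorbing.
#'
#' @param age Fruit age(s), physiological days since squaring.
#' @param arch An [arch_params] list.
#' @return Character vector of stages.
#' @export
fruit_stage <- function(age, arch = arch_params()) stage_of_age(age, arch)

#' One abscission draw for a set of fruits
#'
#' Each living, closed fruit abscises with the daily probability its age maps
#' to in the abscission table; draws come from the session RNG, so a fixed
#' seed reproduces them.
#'
#' @param fruits Data frame with columns `age`, `stage`, `fate`.
#' @param table Abscission table, see [default_abscission_table()].
#' @return The data frame with updated `fate`.
#' @export
abscission_step <- function(fruits, table = default_abscission_table()) {
  sel <- which(fruits$fate == "alive" & fruits$stage != "open-boll")
  if (length(sel)) {
    pr <- abscission_probability(fruits$age[sel], table)
    fruits$fate[sel[stats::runif(length(sel)) < pr]] <- "abscised"
  }
  fruits
}

stage_of_age <- function(age, arch) {
  ifelse(age < arch$dur_square, "square",
    ifelse(age < arch$dur_square + arch$dur_flower, "flower",
      ifelse(age < arch$opening_age, "boll", "open-boll")))
}

#' Top the main stem or the branches
#'
#' Removes the apex and the two topmost phytomers of each affected axis, per
#' common farmer practice; fruits sitting on removed phytomers go with them
#' (recorded with fate `"pruned"`), while fruits on remaining phytomers are
#' untouched. Topping an already-topped axis is a no-op.
#'
#' @param plant A `plant_state`.
#' @param which `"main"` or `"branches"`.
#' @param params A [model_params] list.
#' @return Updated `plant_state`.
#' @export
apply_topping <- function(plant, which = c("main", "branches"),
                          params = model_params()) {
  which <- match.arg(which)
  fr <- plant$fruits
  prune <- function(sel) {
    fr$fate[sel & fr$fate == "alive"] <<- "pruned"
  }
  if (which == "main") {
    if (!plant$main_apex) return(plant)
    plant$main_apex <- FALSE
    new_rank <- max(plant$main_rank - 2L, 0L)
    gone <- as.integer(names(plant$branch_nodes)) > new_rank
    if (nrow(fr)) prune(fr$branch_rank > new_rank)
    plant$branch_nodes <- plant$branch_nodes[!gone]
    plant$branch_cap <- plant$branch_cap[!gone]
    plant$main_rank <- new_rank
  } else {
    if (plant$branch_topped) return(plant)
    plant$branch_topped <- TRUE
    plant$branch_apex <- FALSE
    plant$branch_cap <- pmax(plant$branch_nodes - 2L, 0L)
    names(plant$branch_cap) <- names(plant$branch_nodes)
    if (nrow(fr)) {
      cap <- plant$branch_cap[as.character(fr$branch_rank)]
      cap[is.na(cap)] <- 0L
      prune(fr$node > cap)
    }
  }
  plant$fruits <- fr
  plant
}

#' Advance a plant by one day
#'
#' The daily step: management events scheduled for the day (topping) are
#' applied first; the physiological clock advances by the day's temperature
#' effect; new main-stem phytomers and branch fruiting nodes appear when the
#' clock crosses multiples of the plastochron (an organ of cumulative phytomer
#' number c appears at clock `emergence_lag + c * plastochron`, so equal-CPN
#' fruits are exact age cohorts); living fruits age, accumulate fibre quality
#' (stopping at boll opening), change stage and may abscise with an
#' age-dependent daily probability drawn from the session RNG.
#'
#' @param plant A `plant_state`.
#' @param day One row of a [season_weather] data frame.
#' @param mgmt A [management_params] list.
#' @param params A [model_params] list.
#' @return Updated `plant_state`.
#' @export
advance_plant <- function(plant, day, mgmt, params = model_params()) {
  arch <- params$arch
  p <- plant$plastochron
  date <- day$date

  if (!is.na(mgmt$main_topping_date) && date == mgmt$main_topping_date)
    plant <- apply_topping(plant, "main", params)
  if (!is.na(mgmt$branch_topping_date) && date == mgmt$branch_topping_date)
    plant <- apply_topping(plant, "branches", params)

  old_clock <- plant$clock
  new_clock <- old_clock + daily_temperature_effect(day$t_mean, params$thermal)

  # main-stem phytomer appearance
  while (plant$main_apex &&
         arch$emergence_lag + (plant$main_rank + 1L) * p <= new_clock) {
    plant$main_rank <- plant$main_rank + 1L
    r <- plant$main_rank
    if (r >= arch$first_fruiting_rank) {
      plant$branch_nodes[as.character(r)] <- 0L
      plant$branch_cap[as.character(r)] <-
        if (plant$branch_topped) 0L else arch$nodes_per_branch
    }
  }

  # branch fruiting-node appearance -> new squares
  if (length(plant$branch_nodes)) {
    for (rs in names(plant$branch_nodes)) {
      r <- as.integer(rs)
      while (plant$branch_nodes[[rs]] < plant$branch_cap[[rs]]) {
        j <- plant$branch_nodes[[rs]] + 1L
        cpn <- assign_cpn(r, j)
        sq_clock <- arch$emergence_lag + cpn * p
        if (sq_clock > new_clock) break
        plant$branch_nodes[[rs]] <- j
        plant$fruits <- rbind(plant$fruits, data.frame(
          branch_rank = r, node = j, cpn = cpn,
          squaring_clock = sq_clock, squaring_date = date,
          age = new_clock - sq_clock, stage = "square", fate = "alive",
          length = 0, strength = 0, micronaire = 0,
          stringsAsFactors = FALSE))
      }
    }
  }

  fr <- plant$fruits
  if (nrow(fr)) {
    live <- fr$fate == "alive" & fr$stage != "open-boll" &
      fr$squaring_clock <= new_clock
    if (any(live)) {
      a0 <- pmax(0, old_clock - fr$squaring_clock[live])
      a1 <- new_clock - fr$squaring_clock[live]
      fr$age[live] <- a1
      # quality accrues only up to boll opening
      a1c <- pmin(a1, arch$opening_age)
      a0c <- pmin(a0, arch$opening_age)
      for (idx in c("length", "strength", "micronaire")) {
        fr[[idx]][live] <- fr[[idx]][live] +
          daily_quality_increment(a0c, a1c, idx, day$t_mean, day$t_min,
                                  day$t_range, params$quality)
      }
      fr$stage[live] <- stage_of_age(a1, arch)
      # age-dependent abscission draw for fruits still closed
      closed <- which(live)[fr$stage[live] != "open-boll"]
      if (length(closed)) {
        pr <- abscission_probability(fr$age[closed], arch$abscission)
        drop <- stats::runif(length(closed)) < pr
        fr$fate[closed[drop]] <- "abscised"
      }
    }
  }
  plant$fruits <- fr
  plant$clock <- new_clock
  plant$date <- date
  plant
}

#' Simulate one plant over a season
#'
#' Runs the daily loop from sowing to the end of the weather series (or
#' `end_date`), applying the film-mulch temperature increment first when the
#' management asks for it. All randomness (abscission) flows through `seed`,
#' so a fixed seed reproduces the run exactly.
#'
#' @param weather A [season_weather] covering the season.
#' @param mgmt A [management_params] list.
#' @param params A [model_params] list.
#' @param seed Integer seed.
#' @param end_date Optional last simulated day.
#' @return A `plant_state`; its `$fruits` table holds one row per initiated
#'   fruit with final stage, fate and accumulated length (mm), strength
#'   (cN/tex) and micronaire.
#' @export
simulate_plant <- function(weather, mgmt, params = model_params(), seed = 1L,
                           end_date = NULL) {
  stopifnot(inherits(weather, "season_weather"))
  if (mgmt$film_mulch)
    weather <- apply_film_mulch(weather, params$arch$mulch_delta,
                                start = mgmt$sowing_date,
                                end = mgmt$sowing_date + params$arch$mulch_duration)
  last <- if (is.null(end_date)) max(weather$date) else as.Date(end_date)
  days <- weather[weather$date >= mgmt$sowing_date & weather$date <= last, ]
  if (nrow(days) == 0L) stop("weather does not cover the season")
  set.seed(seed)
  plant <- new_plant(mgmt, params)
  for (i in seq_len(nrow(days)))
    plant <- advance_plant(plant, days[i, ], mgmt, params)
  plant
}

#' Per-fruit results table
#'
#' @param plant A `plant_state` returned by [simulate_plant()].
#' @param plant_id Identifier column to prepend.
#' @return Data frame with one row per initiated fruit: position
#'   (`branch_rank`, `node`, `cpn`), `squaring_date`, `final_stage`,
#'   `abscised` flag, `fate` and final quality values.
#' @export
fruit_table <- function(plant, plant_id = 1L) {
  fr <- plant$fruits
  data.frame(plant_id = plant_id, branch_rank = fr$branch_rank, node = fr$node,
             cpn = fr$cpn, squaring_date = fr$squaring_date,
             final_stage = fr$stage, abscised = fr$fate != "alive",
             fate = fr$fate,
             length_mm = fr$length, strength_cN_tex = fr$strength,
             micronaire = fr$micronaire, stringsAsFactors = FALSE)
}
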