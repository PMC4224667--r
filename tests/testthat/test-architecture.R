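test_that("plastochron map stays in range and responds to density and MC", {
  expect_equal(plastochron(6, FALSE), 3.5)
  for (d in c(0.5, 1, 2, 3.6, 6, 12, 18, 30)) {
    for (mc in c(FALSE, TRUE)) {
      p <- plastochron(d, mc)
      expect_gte(p, 3.0)
      expect_lte(p, 3.5)
    }
    expect_gte(plastochron(d, TRUE), plastochron(d, FALSE))
  }
  d <- c(0.5, 1, 2, 3.6, 6, 12)
  expect_true(all(diff(vapply(d, plastochron, 0)) >= 0))   # denser -> slower
  expect_error(plastochron(0), "positive")
})

test_that("phytomers appear at plastochron multiples; cold days freeze the plant", {
  arch <- arch_params(emergence_lag = 0, first_fruiting_rank = 100L)
  params <- model_params(arch = arch)
  mgmt <- management_params("2007-05-01", density = 6)   # plastochron 3.5
  w <- const_weather(20, 30, from = "2007-05-01", to = "2007-06-04")  # 35 d
  set.seed(1)
  plant <- new_plant(mgmt, params)
  for (i in seq_len(nrow(w))) plant <- advance_plant(plant, w[i, ], mgmt, params)
  expect_equal(plant$main_rank, 10L)      # floor(35 / 3.5)
  expect_equal(plant$clock, 35)

  cold <- const_weather(4, 12, from = "2007-06-05", to = "2007-06-20")
  before <- plant
  for (i in seq_len(nrow(cold))) plant <- advance_plant(plant, cold[i, ], mgmt, params)
  expect_equal(plant$clock, before$clock)
  expect_equal(plant$main_rank, before$main_rank)
  expect_equal(plant$fruits, before$fruits)
  expect_equal(plant$date, as.Date("2007-06-20"))
})

test_that("topping removes the apex and top two phytomers, idempotently", {
  arch <- arch_params(emergence_lag = 0, first_fruiting_rank = 100L)
  params <- model_params(arch = arch)
  mgmt <- management_params("2007-05-01", density = 6)
  w <- const_weather(20, 30, from = "2007-05-01", to = "2007-06-22")  # 53 pd
  set.seed(1)
  plant <- new_plant(mgmt, params)
  for (i in seq_len(nrow(w))) plant <- advance_plant(plant, w[i, ], mgmt, params)
  expect_equal(plant$main_rank, 15L)

  topped <- apply_topping(plant, "main", params)
  expect_equal(topped$main_rank, 13L)
  expect_false(topped$main_apex)
  expect_identical(apply_topping(topped, "main", params), topped)

  # no phytomer ever appears on a topped axis
  more <- const_weather(20, 30, from = "2007-06-23", to = "2007-07-31")
  p2 <- topped
  for (i in seq_len(nrow(more))) p2 <- advance_plant(p2, more[i, ], mgmt, params)
  expect_equal(p2$main_rank, 13L)
})

test_that("branch topping caps every branch at its appeared nodes minus two", {
  arch <- arch_params(nodes_per_branch = 4L,
                      abscission = data.frame(age_from = 0, age_to = Inf,
                                              daily_p = 0))
  params <- model_params(arch = arch)
  mgmt <- management_params("2007-04-25", density = 6)
  w <- const_weather(22, 32, from = "2007-04-25", to = "2007-09-30")
  plant <- simulate_plant(w, mgmt, params, seed = 2)
  full <- names(plant$branch_nodes)[plant$branch_nodes == 4L]
  expect_gt(length(full), 3)

  topped <- apply_topping(plant, "branches", params)
  expect_equal(unname(topped$branch_cap[full]), rep(2L, length(full)))
  alive <- topped$fruits[topped$fruits$fate == "alive", ]
  for (rs in full)
    expect_lte(max(alive$node[alive$branch_rank == as.integer(rs)]), 2L)
  expect_identical(apply_topping(topped, "branches", params), topped)
})

test_that("CPN counts from the cotyledon node and defines exact age cohorts", {
  expect_equal(assign_cpn(7, 1), 8L)               # first node, first branch
  expect_equal(assign_cpn(9, 3) - assign_cpn(9, 2), 1L)
  expect_error(assign_cpn(0, 1), "unknown position")

  w <- const_weather(20, 30, from = "2007-04-25", to = "2007-09-30")
  plant <- simulate_plant(w, std_mgmt(), no_abscission_params(), seed = 4)
  fr <- plant$fruits
  expect_equal(fr$cpn, fr$branch_rank + fr$node)
  per_cpn <- tapply(fr$squaring_clock, fr$cpn, function(x) length(unique(x)))
  expect_true(all(per_cpn == 1))

  # hand timeline at constant optimum (one physiological day per day):
  # fruit of CPN c squares at clock 8 + 3.5 c, i.e. on day ceiling(8 + 3.5 c)
  for (cc in unique(fr$cpn)) {
    sq <- fr[fr$cpn == cc, ][1, ]
    expect_equal(sq$squaring_clock, 8 + 3.5 * cc)
    expect_equal(as.integer(sq$squaring_date - std_mgmt()$sowing_date) + 1L,
                 as.integer(ceiling(8 + 3.5 * cc)))
  }
})

test_that("stage transitions follow the physiological-day thresholds", {
  arch <- arch_params()
  expect_equal(fruit_stage(c(0, 10, 22.9), arch), rep("square", 3))
  expect_equal(fruit_stage(23, arch), "flower")
  expect_equal(fruit_stage(30, arch), "boll")
  expect_equal(fruit_stage(80, arch), "open-boll")   # thresholds 23, 23 + 50
  expect_equal(fruit_stage(73, arch), "open-boll")
  # absorbing: age only grows, and the stage map is monotone in age
  ages <- seq(0, 120, by = 0.5)
  codes <- match(fruit_stage(ages, arch),
                 c("square", "flower", "boll", "open-boll"))
  expect_true(all(diff(codes) >= 0))
})

test_that("abscission matches the analytic survival of its table", {
  # degenerate tables
  fr <- data.frame(age = rep(5, 10), stage = "square", fate = "alive")
  set.seed(1)
  none <- abscission_step(fr, data.frame(age_from = 0, age_to = Inf, daily_p = 0))
  expect_true(all(none$fate == "alive"))
  all_gone <- abscission_step(fr, data.frame(age_from = 0, age_to = Inf,
                                             daily_p = 1))
  expect_true(all(all_gone$fate == "abscised"))

  # Monte-Carlo vs closed-form survival over 1000 fruits ageing 1 pd/day
  tab <- default_abscission_table()
  n <- 1000L
  fr <- data.frame(age = rep(0, n), stage = "square", fate = "alive")
  set.seed(12)
  for (d in 1:73) {
    fr$age <- fr$age + 1
    fr$stage <- fruit_stage(fr$age)
    fr <- abscission_step(fr, tab)
  }
  draws <- (1:73)[fruit_stage(1:73) != "open-boll"]
  s_analytic <- prod(1 - abscission_probability(draws, tab))
  s_emp <- mean(fr$fate == "alive")
  expect_lt(abs(s_emp - s_analytic),
            3 * sqrt(s_analytic * (1 - s_analytic) / n))
})

test_that("fruit conservation holds every simulated day", {
  w <- generate_weather(site_weather_spec("huimin"), seed = 21)
  mgmt <- std_mgmt()
  params <- model_params()
  days <- w[w$date >= mgmt$sowing_date, ]
  set.seed(31)
  plant <- new_plant(mgmt, params)
  n_prev <- 0L
  for (i in seq_len(nrow(days))) {
    plant <- advance_plant(plant, days[i, ], mgmt, params)
    fr <- plant$fruits
    expect_true(all(fr$fate %in% c("alive", "abscised", "pruned")))
    expect_equal(nrow(fr),
                 sum(fr$fate == "alive") + sum(fr$fate == "abscised") +
                   sum(fr$fate == "pruned"))
    expect_gte(nrow(fr), n_prev)           # initiated fruits are never dropped
    n_prev <- nrow(fr)
  }
  expect_gt(n_prev, 10)
})

test_that("earlier main-stem topping never yields more phytomers", {
  w <- const_weather(22, 32, from = "2007-04-25", to = "2007-09-30")
  ranks <- vapply(c("2007-07-10", "2007-07-30", "2007-08-20"), function(d) {
    mgmt <- management_params("2007-04-25", d, "2007-08-25", density = 6)
    simulate_plant(w, mgmt, no_abscission_params(), seed = 9)$main_rank
  }, integer(1))
  expect_true(all(diff(ranks) >= 0))
})
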