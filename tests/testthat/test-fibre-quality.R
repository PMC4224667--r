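test_that("potential quality follows the logistic in age", {
  p <- quality_params()
  for (i in c("length", "strength", "micronaire"))
    expect_equal(potential_quality(p$t_m[[i]], i), p$q_max[[i]] / 2)
  expect_equal(potential_quality(100, "length"), 30.47, tolerance = 0.01 / 30.47)
  expect_equal(potential_quality(100, "strength"), 30.94, tolerance = 0.01 / 30.94)
  expect_equal(potential_quality(100, "micronaire"), 4.648,
               tolerance = 0.01 / 4.648)
  expect_equal(potential_quality(0, "length"), 0.0024, tolerance = 0.05)
  expect_error(potential_quality(-1, "length"), "non-negative")

  ages <- seq(0, 120, by = 0.5)
  for (i in c("length", "strength", "micronaire")) {
    q <- potential_quality(ages, i)
    expect_true(all(diff(q) > 0))
    expect_true(all(q > 0 & q < p$q_max[[i]]))
  }
})

test_that("temperature reduction factors match their fitted forms", {
  # length: unimodal quadratic peaking near 25 C, clamped to [0,1]
  expect_equal(round(stats::optimize(length_mean_temp_factor, c(0, 45),
                                     maximum = TRUE)$maximum), 25)
  expect_gt(length_mean_temp_factor(25, clamp = FALSE), 1)   # raw vertex 1.016
  expect_equal(length_mean_temp_factor(25), 1)
  expect_equal(length_mean_temp_factor(9), 0.0364, tolerance = 1e-6)
  expect_true(length_mean_temp_factor(9) >= 0 && length_mean_temp_factor(9) <= 0.05)
  expect_equal(length_mean_temp_factor(50), 0)

  # strength vs mean: increasing, saturates at 1 above 30 C
  expect_equal(strength_mean_temp_factor(31), 1)
  expect_equal(strength_mean_temp_factor(0), 0.4657)
  expect_equal(strength_mean_temp_factor(20), 0.8617)
  # strength vs diurnal range: decreasing from 1
  expect_equal(strength_td_factor(10), 0.920)
  expect_equal(strength_td_factor(6.3), 1, tolerance = 1e-3)
  expect_equal(strength_td_factor(0), 1)
  expect_error(strength_td_factor(-1), "non-negative")
  # micronaire vs minimum: increasing, saturates at 1 above 25 C
  expect_equal(micronaire_tmin_factor(26), 1)
  expect_equal(micronaire_tmin_factor(0), 0.3874)
  expect_equal(micronaire_tmin_factor(10), 0.6314)

  grid <- seq(-10, 50, by = 0.25)
  expect_true(all(strength_mean_temp_factor(grid) >= 0 &
                  strength_mean_temp_factor(grid) <= 1))
  expect_true(all(diff(strength_mean_temp_factor(grid)) >= 0))
  expect_true(all(diff(micronaire_tmin_factor(grid)) >= 0))
  expect_true(all(diff(strength_td_factor(seq(0, 60, 0.25))) <= 0))
  lf <- length_mean_temp_factor(grid)
  expect_true(all(lf >= 0 & lf <= 1))
})

test_that("daily increments are bounded by the potential and split additively", {
  # fully favourable day (t_min 25.2, t_max 28.8 -> mean 27, range 3.6):
  # every factor clamps to 1, so the actual increment equals the potential
  expect_equal(reduction_factor("length", 27, 25.2, 3.6), 1)
  expect_equal(reduction_factor("strength", 27, 25.2, 3.6), 1)
  expect_equal(reduction_factor("micronaire", 27, 25.2, 3.6), 1)
  pot <- potential_quality(31, "length") - potential_quality(30, "length")
  expect_equal(daily_quality_increment(30, 31, "length", 27, 25.2, 3.6), pot)

  set.seed(7)
  for (rep in seq_len(200)) {
    a0 <- runif(1, 0, 80); a1 <- a0 + runif(1, 0, 1)
    tmin <- runif(1, 0, 28); trng <- runif(1, 0, 18)
    tmean <- tmin + trng / 2
    for (i in c("length", "strength", "micronaire")) {
      d_pot <- potential_quality(a1, i) - potential_quality(a0, i)
      d_act <- daily_quality_increment(a0, a1, i, tmean, tmin, trng)
      expect_gte(d_act, 0)
      expect_lte(d_act, d_pot + 1e-12)
      # one day vs two half-age steps with identical temperatures
      mid <- (a0 + a1) / 2
      expect_equal(d_act,
                   daily_quality_increment(a0, mid, i, tmean, tmin, trng) +
                   daily_quality_increment(mid, a1, i, tmean, tmin, trng))
    }
  }
})

test_that("season-long accumulation converges to q_max under favourable days, 0 at base", {
  p <- quality_params()
  run_days <- function(t_min, t_max, n = 200) {
    t_mean <- (t_min + t_max) / 2; t_rng <- t_max - t_min
    age <- 0; acc <- c(length = 0, strength = 0, micronaire = 0)
    for (d in seq_len(n)) {
      a1 <- min(age + daily_temperature_effect(t_mean), 73)
      for (i in names(acc))
        acc[[i]] <- acc[[i]] +
          daily_quality_increment(min(age, 73), a1, i, t_mean, t_min, t_rng)
      age <- age + daily_temperature_effect(t_mean)
      # running actual never exceeds running potential, never exceeds q_max
      expect_lte(acc[[1]], potential_quality(min(age, 73), "length") + 1e-9)
    }
    acc
  }
  warm <- run_days(25.2, 28.8)
  expect_equal(warm[["length"]], 30.47, tolerance = 0.05 / 30.47)
  cold <- run_days(7, 17)   # t_mean 12 = base: clock frozen
  expect_equal(unname(cold), c(0, 0, 0))
})
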