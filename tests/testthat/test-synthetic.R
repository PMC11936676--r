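test_that("heat-shock generator follows the logistic survival curve", {
  # near-step slope: everyone survives well below the LT50, dies well above
  d <- heat_shock_design(shock_temperatures = c(30, 45),
                         n_per_temperature = 50, true_lt50 = 37.4,
                         true_slope = -10, seed = 11)
  rec <- simulate_heat_shock(d)
  expect_true(all(rec$survived[rec$shock_temperature == 30] == 1))
  expect_true(all(rec$survived[rec$shock_temperature == 45] == 0))

  # at the LT50 the survival fraction is 1/2 (binomial, n = 10000)
  d2 <- heat_shock_design(shock_temperatures = c(37.4, 44),
                          n_per_temperature = 10000, true_lt50 = 37.4,
                          true_slope = -0.25, seed = 12)
  rec2 <- simulate_heat_shock(d2)
  frac <- mean(rec2$survived[rec2$shock_temperature == 37.4])
  expect_lt(abs(frac - 0.5), 0.01)

  # survival fraction tracks the logistic curve within 3 binomial SEs
  d3 <- heat_shock_design(shock_temperatures = seq(30, 45, by = 1),
                          n_per_temperature = 2000, seed = 13)
  rec3 <- simulate_heat_shock(d3)
  frac3 <- tapply(rec3$survived, rec3$shock_temperature, mean)
  temps <- as.numeric(names(frac3))
  p_true <- plogis(-d3$true_slope * d3$true_lt50 + d3$true_slope * temps)
  se <- sqrt(p_true * (1 - p_true) / 2000)
  expect_true(all(abs(frac3 - p_true) < 3 * pmax(se, 1e-6)))
})

test_that("generators are pure functions of design and seed", {
  d <- heat_shock_design(seed = 99)
  expect_identical(simulate_heat_shock(d), simulate_heat_shock(d))
  g <- gradient_design(seed = 99)
  expect_identical(simulate_gradient_trials(g), simulate_gradient_trials(g))
  e <- emergence_design(seed = 99)
  expect_identical(simulate_emergence(e), simulate_emergence(e))
  # a different seed changes the draw
  expect_false(identical(simulate_heat_shock(d),
                         simulate_heat_shock(heat_shock_design(seed = 100))))
})

test_that("invalid designs fail with the offending field named", {
  expect_error(heat_shock_design(true_slope = 0.2), "true_slope")
  expect_error(heat_shock_design(shock_temperatures = c(40, 34)),
               "shock_temperatures")
  expect_error(heat_shock_design(n_per_temperature = 0), "n_per_temperature")
  expect_error(gradient_design(tpref_sd = 0), "tpref_sd")
  expect_error(gradient_design(tpref_mean = 50), "tpref_mean")
  expect_error(gradient_design(bar_cold_end = 45, bar_hot_end = 12),
               "bar_cold_end")
  expect_error(emergence_design(host = list(dd = -1, t0 = 4, noise_sd = 0)),
               "dd")
  # effective temperature must exceed the base temperature
  expect_error(emergence_design(rearing_temperatures = 5,
                                parasitoid = list(dd = 180, t0 = 20,
                                                  noise_sd = 0)),
               "base temperature")
})

test_that("gradient positions concentrate at the preferred temperature", {
  # degenerate preference: everyone at the mark matching the bar midpoint
  d0 <- gradient_design(n_individuals = 200, tpref_mean = 28.5,
                        tpref_sd = 1e-9, n_positions = 7, seed = 3)
  tr0 <- simulate_gradient_trials(d0)
  expect_true(all(tr0$position_gradient == 4))

  # sample mean of implied temperatures matches the truncated-normal
  # oracle (truncation shifts the mean upward off the nominal 20.1)
  d <- gradient_design(n_individuals = 10000, seed = 21)
  tr <- simulate_gradient_trials(d)
  sp <- gradient_spec(d$bar_cold_end, d$bar_hot_end, d$n_positions)
  marks <- position_to_temperature(seq_len(d$n_positions), sp)
  oracle <- disc_truncnorm_moments(d$tpref_mean, d$tpref_sd,
                                   d$bar_cold_end, d$bar_hot_end,
                                   sort(marks))
  got <- mean(position_to_temperature(tr$position_gradient, sp))
  expect_lt(abs(got - oracle$mean), 3 * oracle$sd / sqrt(10000))
  # continuous-position mode matches the numeric-integration oracle
  dc <- gradient_design(n_individuals = 10000, discretize = FALSE, seed = 22)
  trc <- simulate_gradient_trials(dc)
  gotc <- mean(position_to_temperature(trc$position_gradient, sp))
  cont <- truncnorm_mean_oracle(20.1, 4.5, 12.5, 44.5)
  expect_lt(abs(gotc - cont), 3 * 4.5 / sqrt(10000))

  # control (uniform) positions are more dispersed than gradient positions
  d2 <- gradient_design(n_individuals = 1000, seed = 5)
  tr2 <- simulate_gradient_trials(d2)
  expect_gt(var(tr2$position_control), var(tr2$position_gradient))
  # and close to their analytic variances
  expect_lt(abs(var(tr2$position_control) - (6^2 - 1) / 12), 0.4)
})

test_that("emergence times follow the degree-day model", {
  # closed form: dd / (t_eff - t0) with no noise
  t_day <- (20 * 24 - 10 * 10) / 14  # daytime max giving t_eff = 20
  expect_equal(effective_rearing_temperature(t_day), 20)
  d <- emergence_design(
    rearing_temperatures = t_day, n_leaves_per_temperature = 50,
    host = list(dd = 300, t0 = 5, noise_sd = 0),
    parasitoid = list(dd = 300, t0 = 5, noise_sd = 0),
    emergence_probability = c(host = 0.5, parasitoid = 0.5), seed = 4
  )
  rec <- simulate_emergence(d)
  expect_true(all(rec$days_to_emergence == 300 / (20 - 5)))

  # noise-free means strictly decrease with rearing temperature
  d2 <- emergence_design(
    host = list(dd = 250, t0 = 4, noise_sd = 0),
    parasitoid = list(dd = 165, t0 = 9.5, noise_sd = 0), seed = 6
  )
  rec2 <- simulate_emergence(d2)
  for (ty in c("host", "parasitoid")) {
    m <- tapply(rec2$days_to_emergence[rec2$insect_type == ty],
                rec2$rearing_temperature[rec2$insect_type == ty], mean)
    expect_true(all(diff(m) < 0))
  }

  # default parameters: parasitoids slower than hosts at the coldest
  # rearing temperature, faster at the warmest (the crossing interaction)
  d3 <- emergence_design(n_leaves_per_temperature = 2000, seed = 7)
  rec3 <- simulate_emergence(d3)
  mn <- tapply(rec3$days_to_emergence,
               list(rec3$insect_type, rec3$rearing_temperature), mean)
  expect_gt(mn["parasitoid", "15"], mn["host", "15"])
  expect_lt(mn["parasitoid", "35"], mn["host", "35"])

  # zero emergence probability gives an empty record set
  d4 <- emergence_design(emergence_probability =
                           c(host = 0, parasitoid = 0), seed = 8)
  expect_identical(nrow(simulate_emergence(d4)), 0L)
})
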