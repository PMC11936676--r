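test_that("position-temperature mapping is the exact linear gradient", {
  sp <- gradient_spec(12.5, 44.5, 6)  # cold end at mark 6
  expect_equal(position_to_temperature(6, sp), 12.5)
  expect_equal(position_to_temperature(1, sp), 44.5)
  expect_equal(position_to_temperature(5, sp), 18.9)
  sp7 <- gradient_spec(12.5, 44.5, 7)
  expect_equal(position_to_temperature(4, sp7), 28.5)  # midpoint mark
  spf <- gradient_spec(12.5, 44.5, 6, cold_end_position = "first")
  expect_equal(position_to_temperature(1, spf), 12.5)
  # affine: second differences across consecutive marks vanish
  temps <- position_to_temperature(1:6, sp)
  expect_equal(max(abs(diff(diff(temps)))), 0)
  expect_error(position_to_temperature(7, sp), "within")
  expect_error(position_to_temperature(0.5, sp), "within")
})

test_that("variance-equality test matches hand-computed sums of squares", {
  got <- levene_test(c(1, 2, 3), c(1, 5, 9), center = "median")
  expect_equal(got$F, 72 / 34, tolerance = 1e-12)
  expect_equal(got$df, c(1L, 4L))

  # identical groups carry no variance difference
  expect_equal(levene_test(c(1, 2, 3), c(1, 2, 3))$F, 0)
  expect_error(levene_test(c(2, 2, 2), c(5, 5, 5)), "undefined")
  expect_error(levene_test(1, c(1, 2)), "at least 2")

  # agreement with the textbook oracle (and car) on random data
  withr::with_seed(61, {
    for (i in 1:100) {
      a <- rnorm(sample(4:12, 1), sd = runif(1, 0.5, 3))
      b <- runif(sample(4:12, 1), -2, 2)
      for (ctr in c("median", "mean")) {
        got <- levene_test(a, b, center = ctr)
        ora <- levene_oracle(a, b,
                             center = if (ctr == "median") median else mean)
        expect_equal(got$F, ora$F, tolerance = 1e-10)
        expect_equal(got$p, ora$p, tolerance = 1e-10)
      }
    }
    a <- rnorm(30); b <- rnorm(30, sd = 2)
    cl <- car::leveneTest(c(a, b), factor(rep(1:2, each = 30)))
    expect_equal(levene_test(a, b)$F, cl[1, "F value"], tolerance = 1e-10)
  })
})

test_that("gradient assays separate control and preference variance", {
  # power: uniform control vs preference-concentrated gradient positions
  hits <- 0L
  for (s in 1:500) {
    tr <- simulate_gradient_trials(gradient_design(n_individuals = 136,
                                                   seed = 1000 + s))
    p <- levene_test(tr$position_control, tr$position_gradient)$p
    if (p < 0.005) hits <- hits + 1L
  }
  expect_gte(hits / 500, 0.95)
})

test_that("paired position test matches the one-sample t formula", {
  tr <- data.frame(position_control = c(1, 1, 1),
                   position_gradient = c(2, 3, 4))
  got <- paired_position_test(tr)
  expect_equal(got$mean_diff, 2)
  expect_equal(got$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(got$df, 2)

  expect_error(paired_position_test(
    data.frame(position_control = 1:3, position_gradient = 1:3)
  ), "zero variance")

  withr::with_seed(62, {
    for (i in 1:100) {
      n <- sample(3:20, 1)
      tr <- data.frame(position_control = runif(n, 1, 6),
                       position_gradient = runif(n, 1, 6))
      got <- paired_position_test(tr)
      ora <- paired_t_oracle(tr$position_gradient - tr$position_control)
      expect_equal(got$t, ora$t, tolerance = 1e-10)
      expect_equal(got$p, ora$p, tolerance = 1e-10)
    }
  })

  # a preference run of the apparatus size leaves n - 1 df
  tr135 <- simulate_gradient_trials(gradient_design(n_individuals = 135,
                                                    seed = 63))
  expect_equal(paired_position_test(tr135)$df, 134)
})

test_that("preferred-temperature summaries reconstruct the Student-t CI", {
  ci <- tpref_ci(20.1, 4.5, 135)
  expect_equal(round(unname(ci), 1), c(19.3, 20.9))
  ci4 <- tpref_ci(20, sd(c(18, 19, 21, 22)), 4)
  expect_equal(unname(ci4),
               20 + c(-1, 1) * qt(0.975, 3) * sd(c(18, 19, 21, 22)) / 2,
               tolerance = 1e-12)

  s <- summarize_tpref(c(18, 19, 21, 22))
  expect_equal(s$mean, 20)
  expect_equal(s$sd, sd(c(18, 19, 21, 22)))
  # constant sample: the interval collapses to the point
  s0 <- summarize_tpref(rep(20.1, 10))
  expect_equal(s0$sd, 0)
  expect_equal(unname(s0$ci95), c(20.1, 20.1))
  expect_error(summarize_tpref(20.1), "at least 2")
})

test_that("rearing-temperature ANOVA is calibrated under the null", {
  withr::with_seed(64, {
    pvals <- replicate(250, {
      rearing <- rep(c(15, 20, 25, 30, 35), length.out = 5000)
      tp <- rnorm(5000, 20.1, 4.5)  # independent of rearing
      anova_tpref_by_rearing(tp, rearing)$p
    })
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)

  # strong injected effect is detected
  withr::with_seed(65, {
    rearing <- rep(c(15, 20, 25, 30, 35), length.out = 500)
    tp <- 10 + 0.5 * rearing + rnorm(500, 0, 2)
    res <- anova_tpref_by_rearing(tp, rearing)
  })
  expect_lt(res$p, 0.001)
  expect_equal(res$df, c(1L, 498L))

  # exact dependence is flagged rather than reported as a finite F
  perf <- anova_tpref_by_rearing(c(15, 20, 25, 30), c(15, 20, 25, 30))
  expect_true(perf$perfect_fit)
  expect_identical(perf$F, Inf)
  expect_error(anova_tpref_by_rearing(1:5, rep(20, 5)), "constant")
})

test_that("preference pipeline attains nominal CI coverage", {
  d0 <- gradient_design(n_individuals = 135, seed = 1)
  sp <- gradient_spec(d0$bar_cold_end, d0$bar_hot_end, d0$n_positions)
  marks <- sort(position_to_temperature(seq_len(d0$n_positions), sp))
  pop <- disc_truncnorm_moments(d0$tpref_mean, d0$tpref_sd,
                                d0$bar_cold_end, d0$bar_hot_end, marks)
  covered <- 0L
  for (s in 1:1000) {
    tr <- simulate_gradient_trials(gradient_design(n_individuals = 135,
                                                   seed = 2000 + s))
    tp <- summarize_tpref(position_to_temperature(tr$position_gradient, sp))
    if (tp$ci95[["lower"]] <= pop$mean && pop$mean <= tp$ci95[["upper"]]) {
      covered <- covered + 1L
    }
  }
  expect_gte(covered / 1000, 0.93)
})

test_that("preference_summary assembles all components coherently", {
  tr <- simulate_gradient_trials(gradient_design(n_individuals = 135,
                                                 seed = 66))
  ps <- preference_summary(tr)
  expect_s3_class(ps, "preference_summary")
  expect_equal(ps$n, 135)
  expect_equal(ps$paired$df, 134)
  expect_lt(ps$levene$p, 0.05)
  expect_true(ps$tpref$ci95[["lower"]] < ps$tpref$mean)
  expect_true(ps$tpref$mean < ps$tpref$ci95[["upper"]])
  expect_output(print(ps), "Thermal preference")
})
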