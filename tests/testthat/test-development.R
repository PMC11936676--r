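test_that("emergence linear model recovers exact and noisy surfaces", {
  # noise-free data from a known linear surface are interpolated exactly
  temps <- rep(c(15, 20, 25, 30, 35), each = 4)
  type <- rep(rep(c("host", "parasitoid"), each = 2), 5)
  days <- 40 - 0.8 * temps + 3 * (type == "parasitoid") -
    0.1 * temps * (type == "parasitoid")
  fit <- fit_emergence_lm(data.frame(insect_type = type,
                                     rearing_temperature = temps,
                                     days_to_emergence = days))
  expect_equal(unname(fit$coefficients), c(40, -0.8, 3, -0.1),
               tolerance = 1e-10)
  expect_lt(fit$rss, 1e-18)

  # residual SS agrees with an independent normal-equations solver
  withr::with_seed(71, {
    for (i in 1:5) {
      n <- 40
      temps <- sample(c(15, 20, 25, 30, 35), n, replace = TRUE)
      type <- sample(c("host", "parasitoid"), n, replace = TRUE)
      days <- 30 - 0.5 * temps + rnorm(n, 0, 2) +
        2 * (type == "parasitoid")
      rec <- data.frame(insect_type = type, rearing_temperature = temps,
                        days_to_emergence = pmax(days, 1))
      fit <- fit_emergence_lm(rec)
      ind <- as.numeric(type == sort(unique(type))[2])
      ora <- ols_oracle(rec$days_to_emergence,
                        cbind(1, temps, ind, temps * ind))
      expect_equal(fit$rss, ora$rss, tolerance = 1e-8)
      expect_equal(unname(fit$coefficients), unname(ora$coefficients),
                   tolerance = 1e-8)
    }
  })

  expect_error(fit_emergence_lm(data.frame(
    insect_type = "host", rearing_temperature = c(15, 20),
    days_to_emergence = c(30, 20)
  )), "both insect types")
  expect_error(fit_emergence_lm(data.frame(
    insect_type = c("host", "parasitoid"), rearing_temperature = 20,
    days_to_emergence = c(30, 20)
  )), "rearing_temperature")
})

test_that("sequential ANOVA decomposes the corrected total sum of squares", {
  rec <- simulate_emergence(emergence_design(seed = 72))
  fit <- fit_emergence_lm(rec)
  tab <- anova_sequential(fit)
  # additivity: term + residual SS = total corrected SS
  total <- sum((rec$days_to_emergence - mean(rec$days_to_emergence))^2)
  expect_equal(sum(tab$sum_sq), total, tolerance = 1e-8)
  expect_equal(sum(tab$df), fit$n - 1)

  # against the independent sequential oracle
  ind <- as.numeric(rec$insect_type == "parasitoid")
  ora <- seq_ss_oracle(rec$days_to_emergence,
                       list(rec$rearing_temperature, ind,
                            rec$rearing_temperature * ind))
  expect_equal(tab$sum_sq[1:3], ora$ss, tolerance = 1e-8)
  expect_equal(tab$sum_sq[4], ora$rss, tolerance = 1e-8)

  # balanced orthogonal design: sequential equals marginal SS
  temps <- rep(c(-1, 1), each = 20)
  type <- rep(rep(c("host", "parasitoid"), each = 10), 2)
  withr::with_seed(73, days <- 20 + temps + rnorm(40))
  bal <- data.frame(insect_type = type, rearing_temperature = temps + 25,
                    days_to_emergence = days)
  t1 <- anova_sequential(fit_emergence_lm(bal))
  bal2 <- bal  # refit with type entered first via relabelled column order
  ind2 <- as.numeric(bal2$insect_type == "parasitoid")
  o_type_first <- seq_ss_oracle(bal2$days_to_emergence,
                                list(ind2, bal2$rearing_temperature,
                                     bal2$rearing_temperature * ind2))
  expect_equal(t1$sum_sq[t1$term == "type"], o_type_first$ss[1],
               tolerance = 1e-8)
})

test_that("null type effects give uniform p-values across seeds", {
  pvals <- t(vapply(1:500, function(s) {
    withr::with_seed(3000 + s, {
      temps <- rep(c(15, 20, 25, 30, 35), each = 20)
      type <- rep(c("host", "parasitoid"), 50)
      days <- 40 - 0.7 * temps + rnorm(100, 0, 3)
      tab <- anova_sequential(fit_emergence_lm(data.frame(
        insect_type = type, rearing_temperature = temps,
        days_to_emergence = pmax(days, 1)
      )))
      c(type = tab$p[tab$term == "type"],
        interaction = tab$p[grepl(":", tab$term)])
    })
  }, numeric(2)))
  expect_gt(stats::ks.test(pvals[, "type"], "punif")$p.value, 0.01)
  expect_gt(stats::ks.test(pvals[, "interaction"], "punif")$p.value, 0.01)
})

test_that("default emergence design yields all terms significant", {
  rec <- simulate_emergence(emergence_design(seed = 74))
  expect_gt(nrow(rec), 300)  # comparable to a 750-leaf field collection
  tab <- anova_sequential(fit_emergence_lm(rec))
  expect_true(all(tab$p[1:3] < 0.001))
})

test_that("Gaussian ML AIC follows the closed form", {
  fake <- list(rss = 10, n = 10, coefficients = c(a = 1, b = 2))
  expect_equal(lm_aic(fake), 10 * log(2 * pi) + 10 * log(1) + 10 + 6)

  rec <- simulate_emergence(emergence_design(seed = 75))
  fit <- fit_emergence_lm(rec)
  expect_equal(lm_aic(fit), AIC(fit$lm), tolerance = 1e-8)

  # adding a pure-noise regressor changes AIC by 2 - n log(rss0/rss1)
  y <- rec$days_to_emergence
  X0 <- cbind(1, rec$rearing_temperature)
  withr::with_seed(76, X1 <- cbind(X0, rnorm(nrow(rec))))
  f0 <- ols_oracle(y, X0)
  f1 <- ols_oracle(y, X1)
  a0 <- lm_aic(list(rss = f0$rss, n = length(y), coefficients = 1:2))
  a1 <- lm_aic(list(rss = f1$rss, n = length(y), coefficients = 1:3))
  expect_equal(a1 - a0, 2 - length(y) * log(f0$rss / f1$rss),
               tolerance = 1e-10)
  expect_lte(f1$rss, f0$rss)  # nested models: RSS monotone

  expect_error(lm_aic(list(rss = 0, n = 10, coefficients = 1:2)),
               "degenerate")
})

test_that("development rates invert emergence times", {
  rec <- data.frame(insect_type = "host", rearing_temperature = 20,
                    days_to_emergence = 20)
  expect_equal(development_rate(rec)$rate, 0.05)
  empty <- rec[0, ]
  expect_identical(nrow(development_rate(empty)), 0L)

  # monotone increasing rate with temperature for noise-free data
  d <- emergence_design(host = list(dd = 250, t0 = 4, noise_sd = 0),
                        parasitoid = list(dd = 165, t0 = 9.5, noise_sd = 0),
                        seed = 77)
  rec2 <- development_rate(simulate_emergence(d))
  m <- tapply(rec2$rate[rec2$insect_type == "host"],
              rec2$rearing_temperature[rec2$insect_type == "host"], mean)
  expect_true(all(diff(m) > 0))
})

test_that("emergence bookkeeping converts counts to proportions", {
  tab <- emergence_proportions(750, c(host = 107, parasitoid = 270))
  expect_equal(tab$proportion[tab$outcome == "parasitoid"], 0.36)
  expect_equal(tab$count[tab$outcome == "none"], 373)
  expect_equal(sum(tab$proportion), 1)
  expect_error(emergence_proportions(10, c(host = 11)), "at most")
})
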